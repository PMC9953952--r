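#' Sentence relevance (X-Factor)
#'
#' Relevance of an explanation sentence, combining the classifier's
#' attribution for the supporting nodes (contribution, signed) with the
#' physician-assigned importance of their node type (impact, nonnegative):
#' `sigmoid(contribution * impact)`. Strictly increasing in the contribution
#' for positive impact; 0.5 exactly when either term is zero.
#'
#' @param contribution signed attribution value.
#' @param impact nonnegative importance weight.
#' @return value in `(0, 1)`.
#' @export
#' @examples
#' x_factor(2, 3) # 1 / (1 + exp(-6))
x_factor <- function(contribution, impact) {
  if (any(impact < 0)) {
    stop_kgx("impact must be nonnegative", "kgx_validation_error")
  }
  plogis(contribution * impact)
}

#' Node-type importance table (X-Impact)
#'
#' Importance weights per node type. Defaults encode that a database listing
#' itself is important information to a physician: ClinVar records weigh
#' most, then COSMIC, then per-algorithm scores and publications; anything
#' else gets the baseline. Fully overridable, or loadable from YAML via
#' [load_explainer_config()].
#'
#' @param ... named overrides, e.g. `clinvar_record = 3`.
#' @param baseline weight for node types not listed.
#' @return named numeric vector with a `baseline` attribute.
#' @export
x_impacts <- function(..., baseline = 0.5) {
  w <- c(
    clinvar_record = 2.0, cosmic_record = 1.5, dbnsfp_score = 1.0,
    publication = 1.0
  )
  dots <- c(...)
  if (length(dots)) w[names(dots)] <- dots
  attr(w, "baseline") <- baseline
  w
}

impact_of <- function(impacts, node_type) {
  v <- unname(impacts[node_type])
  v[is.na(v)] <- attr(impacts, "baseline") %||% 0.5
  v
}

#' Aggregate contribution of a matched node set
#'
#' Signed maximum-magnitude contribution over the supporting nodes
#' (consistent with the edge-to-node aggregation of [node_contributions()]);
#' 0 for an empty set.
#'
#' @param node_set character vector of node ids.
#' @param node_contribs named numeric vector from [node_contributions()].
#' @return a single signed value.
#' @export
sentence_contribution <- function(node_set, node_contribs) {
  v <- node_contribs[intersect(node_set, names(node_contribs))]
  if (!length(v)) return(0)
  as.numeric(v[which.max(abs(v))])
}

SIGNIFICANCE_SEVERITY <- c(
  "Pathogenic", "Likely_pathogenic", "VUS", "Likely_benign", "Benign"
)

modal_value <- function(x, priority = NULL) {
  tab <- table(x)
  top <- names(tab)[tab == max(tab)]
  if (!is.null(priority)) {
    ord <- match(top, priority)
    top <- top[order(ord)]
  } else {
    top <- sort(top)
  }
  top[1]
}

join_items <- function(items) {
  n <- length(items)
  if (n == 1) return(items)
  paste0(paste(items[-n], collapse = ", "), ", and ", items[n])
}

# shared pre-extracted view of an explanation subgraph
explain_context <- function(fg) {
  recs <- fg_records(fg)
  lits <- fg_literals(fg)
  nd <- fg$nodes
  tgt <- recs[recs$hub == fg$target_hub, ]
  lit_of <- function(rec, pred) {
    v <- lits$value[lits$subject %in% rec & lits$predicate == pred]
    if (length(v)) v else NA_character_
  }
  list(fg = fg, recs = recs, lits = lits, nodes = nd, tgt = tgt,
       lit_of = lit_of)
}

# ---- the ten rules -------------------------------------------------------

rule_neighboring_clinvar <- list(
  name = "Neighboring variants in ClinVar",
  cardinality = "one-per-variant",
  match = function(ctx) {
    nbl <- ctx$fg$neighbor_links
    nb <- ctx$recs[ctx$recs$hub %in% nbl$hub & ctx$recs$rec_type == "clinvar_record", ]
    if (!nrow(nb)) return(list())
    cons <- vapply(nb$rec, function(r) ctx$lit_of(r, "consequence")[1], character(1))
    sig <- vapply(nb$rec, function(r) ctx$lit_of(r, "clinical_significance")[1],
                  character(1))
    ok <- !is.na(cons)
    if (!any(ok)) return(list())
    co <- modal_value(cons[ok])
    sel <- ok & cons == co
    key_of <- nbl$key[match(nb$hub, nbl$hub)]
    n_total <- length(unique(key_of[sel]))
    # report the most severe significance present among these neighbors
    sig_sel <- sig[sel]
    s <- SIGNIFICANCE_SEVERITY[SIGNIFICANCE_SEVERITY %in% sig_sel][1]
    if (is.na(s)) return(list())
    n_sig <- length(unique(key_of[sel & !is.na(sig) & sig == s]))
    if (n_sig < 1) return(list())
    list(list(
      slots = list(n_total = n_total, consequence = co, n_sig = n_sig,
                   significance = s),
      support = nb$rec[sel]
    ))
  },
  render = function(slots) {
    sprintf("%s neighboring %s \u201c%s\u201d, %s of which %s registered as \u201c%s\u201d in ClinVar.",
            cap_first(num_to_words(slots$n_total)),
            if (slots$n_total == 1) "variant is" else "variants are",
            humanize_term(slots$consequence),
            num_to_words(slots$n_sig),
            if (slots$n_sig == 1) "is" else "are",
            humanize_term(slots$significance))
  }
)

target_scores <- function(ctx) {
  db <- ctx$tgt[ctx$tgt$rec_type == "dbnsfp_record", ]
  if (!nrow(db)) {
    return(data.table::data.table(node = character(), alg = character(),
                                  score = numeric()))
  }
  sl <- ctx$lits[ctx$lits$subject %in% db$rec &
                   startsWith(ctx$lits$predicate, "score:"), ]
  data.table::data.table(
    node = sl$object, alg = sub("^score:", "", sl$predicate),
    score = as.numeric(sl$value)
  )
}

rule_outstanding <- list(
  name = "Outstanding algorithms in dbNSFP",
  cardinality = "one-per-variant",
  match = function(ctx) {
    sc <- target_scores(ctx)
    sc <- sc[!is.na(sc$score) & sc$score >= 0.5, ]
    if (!nrow(sc)) return(list())
    sc <- sc[order(-sc$score, sc$alg), ]
    list(list(
      slots = list(alg = sc$alg, score = sc$score,
                   qual = ifelse(sc$score >= 0.7, "high", "moderate")),
      support = sc$node
    ))
  },
  render = function(slots) {
    items <- sprintf("%s is %s (%.2f)", slots$alg, slots$qual, slots$score)
    sprintf("This variant has dbNSFP algorithms: %s.", join_items(items))
  }
)

rule_average <- list(
  name = "Average of algorithms in dbNSFP",
  cardinality = "one-per-variant",
  match = function(ctx) {
    sc <- target_scores(ctx)
    sc <- sc[!is.na(sc$score), ]
    is_cons <- sc$alg %in% CONSERVATION_ALGORITHMS
    if (!any(is_cons) || !any(!is_cons)) return(list())
    list(list(
      slots = list(
        mean_pred = mean(sc$score[!is_cons]), n_pred = sum(!is_cons),
        mean_cons = mean(sc$score[is_cons]), n_cons = sum(is_cons)
      ),
      support = sc$node
    ))
  },
  render = function(slots) {
    sprintf("This variant has an average score of %.2f for %d prediction algorithms, and %.2f for %d conservation algorithms from dbNSFP.",
            slots$mean_pred, slots$n_pred, slots$mean_cons, slots$n_cons)
  }
)

rule_same_aa <- list(
  name = "Same amino acid variants",
  cardinality = "one-per-variant",
  match = function(ctx) {
    nbl <- ctx$fg$neighbor_links
    same <- nbl[nbl$distance == 0, ]
    if (!nrow(same)) return(list())
    nb <- ctx$recs[ctx$recs$hub %in% same$hub &
                     ctx$recs$rec_type == "clinvar_record", ]
    if (!nrow(nb)) return(list())
    sig <- vapply(nb$rec, function(r) ctx$lit_of(r, "clinical_significance")[1],
                  character(1))
    sig <- sig[!is.na(sig)]
    if (!length(sig)) return(list())
    list(list(
      slots = list(
        significance = SIGNIFICANCE_SEVERITY[SIGNIFICANCE_SEVERITY %in% sig][1]
      ),
      support = nb$rec
    ))
  },
  render = function(slots) {
    sprintf("Neighboring variants in the same base are registered as \"%s\" in ClinVar.",
            slots$significance)
  }
)

rule_papers <- list(
  name = "Neighboring variant papers",
  cardinality = "one-per-variant",
  match = function(ctx) {
    nbl <- ctx$fg$neighbor_links
    nb <- ctx$recs[ctx$recs$hub %in% nbl$hub, ]
    if (!nrow(nb)) return(list())
    pub <- ctx$lits[ctx$lits$subject %in% nb$rec &
                      ctx$lits$predicate == "has_publication", ]
    if (!nrow(pub)) return(list())
    key_of <- nbl$key[match(nb$hub, nbl$hub)]
    names(key_of) <- nb$rec
    n_var <- length(unique(key_of[pub$subject]))
    n_papers <- length(unique(pub$value))
    list(list(
      slots = list(n_var = n_var, n_papers = n_papers),
      support = unique(pub$object)
    ))
  },
  render = function(slots) {
    sprintf("%s neighboring %s reported in %s %s.",
            cap_first(num_to_words(slots$n_var)),
            if (slots$n_var == 1) "variant is" else "variants are",
            num_to_words(slots$n_papers),
            if (slots$n_papers == 1) "paper" else "papers")
  }
)

rule_cosmic <- list(
  name = "Variants in COSMIC",
  cardinality = "one-per-match",
  match = function(ctx) {
    nbl <- ctx$fg$neighbor_links
    nb <- ctx$recs[ctx$recs$hub %in% nbl$hub & ctx$recs$rec_type == "cosmic_record", ]
    if (!nrow(nb)) return(list())
    out <- list()
    for (i in seq_len(nrow(nb))) {
      pc <- ctx$lit_of(nb$rec[i], "protein_change")[1]
      if (is.na(pc)) next
      out[[length(out) + 1L]] <- list(
        slots = list(protein_change = pc), support = nb$rec[i]
      )
    }
    out
  },
  render = function(slots) {
    sprintf("A neighboring variant, %s, is registered in COSMIC.",
            slots$protein_change)
  }
)

rule_dbnsfp <- list(
  name = "Variants in dbNSFP",
  cardinality = "one-per-match",
  match = function(ctx) {
    sc <- target_scores(ctx)
    sc <- sc[!is.na(sc$score), ]
    lapply(seq_len(nrow(sc)), function(i) {
      list(slots = list(alg = sc$alg[i], score = sc$score[i]),
           support = sc$node[i])
    })
  },
  render = function(slots) {
    sprintf("This variant has a score of %.2f according to the %s algorithm of dbNSFP.",
            slots$score, slots$alg)
  }
)

rule_reference <- list(
  name = "Variants reference",
  cardinality = "one-per-match",
  match = function(ctx) {
    pub <- ctx$lits[ctx$lits$subject %in% ctx$tgt$rec &
                      ctx$lits$predicate == "has_publication", ]
    lapply(seq_len(nrow(pub)), function(i) {
      list(slots = list(pmid = pub$value[i]), support = pub$object[i])
    })
  },
  render = function(slots, accessed_date = "2 December 2022") {
    sprintf("This variant is explained in https://pubmed.ncbi.nlm.nih.gov/%s/ (accessed on %s).",
            slots$pmid, accessed_date)
  }
)

rule_clinvar <- list(
  name = "Variants in ClinVar",
  cardinality = "one-per-match",
  match = function(ctx) {
    cv <- ctx$tgt[ctx$tgt$rec_type == "clinvar_record", ]
    lapply(cv$rec, function(r) {
      list(slots = list(
        significance = ctx$lit_of(r, "clinical_significance")[1],
        stars = ctx$lit_of(r, "review_stars")[1],
        n_submissions = ctx$lit_of(r, "n_submissions")[1]
      ), support = r)
    })
  },
  render = function(slots) {
    sprintf("This variant is considered %s with %s stars in ClinVar, and the report has %s submissions.",
            tolower(humanize_term(slots$significance)), slots$stars,
            slots$n_submissions)
  }
)

rule_type <- list(
  name = "Variants type",
  cardinality = "one-per-variant",
  match = function(ctx) {
    # consequence literal on the target hub, else from a target ClinVar record
    v <- ctx$lits$value[ctx$lits$subject == ctx$fg$target_hub &
                          ctx$lits$predicate == "consequence"]
    if (!length(v)) {
      cv <- ctx$tgt$rec[ctx$tgt$rec_type == "clinvar_record"]
      if (length(cv)) v <- ctx$lit_of(cv, "consequence")
    }
    v <- v[!is.na(v)]
    if (!length(v)) return(list())
    sup <- ctx$lits$object[ctx$lits$predicate == "consequence" &
                             (ctx$lits$subject == ctx$fg$target_hub |
                                ctx$lits$subject %in% ctx$tgt$rec)]
    list(list(slots = list(consequence = v[1]), support = sup))
  },
  render = function(slots) {
    sprintf("This variant is a %s.", humanize_term(slots$consequence))
  }
)

#' The explanation rule set (X-Rules)
#'
#' Declarative rules turning matched node sets of the explanation subgraph
#' into sentences, in the fixed order used for tie-breaking. Each rule has a
#' `name`, a `cardinality` (one aggregate sentence per variant, or one per
#' matched node set), a `match(ctx)` function returning node sets with bound
#' slots, and a `render(slots)` template.
#'
#' @param accessed_date date string printed by the literature-reference rule.
#' @param names optional subset of rule names to enable, in the given order.
#' @return ordered list of rules.
#' @export
x_rules <- function(accessed_date = "2 December 2022", names = NULL) {
  ref <- rule_reference
  render0 <- ref$render
  ref$render <- function(slots) render0(slots, accessed_date)
  rules <- list(
    rule_neighboring_clinvar, rule_outstanding, rule_average, rule_same_aa,
    rule_papers, rule_cosmic, rule_dbnsfp, ref, rule_clinvar, rule_type
  )
  rule_names <- vapply(rules, `[[`, character(1), "name")
  if (!is.null(names)) {
    miss <- setdiff(names, rule_names)
    if (length(miss)) {
      stop_kgx(paste("unknown rule(s):", paste(miss, collapse = ", ")),
               "kgx_validation_error")
    }
    rules <- rules[match(names, rule_names)]
  }
  stats::setNames(rules, vapply(rules, `[[`, character(1), "name"))
}

#' Match one rule against an explanation subgraph
#'
#' @param rule an element of [x_rules()].
#' @param fg a `kgx_feature_graph` built in explanation mode.
#' @return list of matches, each with `slots` and `support` (node ids);
#'   empty list when the rule does not apply.
#' @export
match_rule <- function(rule, fg) {
  if (fg$mode != "explanation") {
    stop_kgx("rules match against explanation-mode subgraphs", "kgx_mode_error")
  }
  rule$match(explain_context(fg))
}

#' Render a matched rule into a sentence
#'
#' @param rule an element of [x_rules()].
#' @param match one match from [match_rule()].
#' @return the rendered sentence.
#' @export
render_sentence <- function(rule, match) {
  slots <- if (!is.null(match$slots)) match$slots else match
  need <- any(vapply(slots, function(s) any(is.na(s)), logical(1)))
  if (need) stop_kgx("unbound template slot", "kgx_render_error")
  rule$render(slots)
}

#' Load impact table and rule settings from YAML
#'
#' Schema: top-level keys `impacts` (map node type to weight, optional
#' `baseline`), `accessed_date`, and `rules` (ordered list of enabled rule
#' names).
#'
#' @param path YAML file path.
#' @return list with `impacts`, `rules` and `accessed_date`.
#' @export
load_explainer_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  imp <- cfg$impacts %||% list()
  baseline <- imp$baseline %||% 0.5
  imp$baseline <- NULL
  impacts <- do.call(x_impacts, c(lapply(imp, as.numeric), baseline = baseline))
  accessed <- cfg$accessed_date %||% "2 December 2022"
  list(
    impacts = impacts,
    rules = x_rules(accessed_date = accessed, names = unlist(cfg$rules)),
    accessed_date = accessed
  )
}

#' Generate ranked explanation sentences for a variant
#'
#' Builds the explanation-mode feature subgraph for the target, scores it
#' with the explanation model, attributes the score to edges and nodes
#' ([edge_contributions()], [node_contributions()]), applies every rule to
#' the subgraph, and ranks the rendered sentences by descending X-Factor
#' (ties broken by rule order, then by text).
#'
#' @param model a `kgx_model` trained in explanation mode.
#' @param target canonical variant key.
#' @param kg the integrated knowledge graph.
#' @param index a [variant_index()].
#' @param rules rule set, default [x_rules()].
#' @param impacts impact table, default [x_impacts()].
#' @param top_n maximum number of sentences (>= 1).
#' @param n_perturbations,seed passed to [edge_contributions()].
#' @return tibble with columns `rank, rule, text, x_factor, contribution,
#'   impact, score, support` (list column of node ids), at most `top_n` rows,
#'   sorted by descending `x_factor`.
#' @export
explain_variant <- function(model, target, kg, index, rules = x_rules(),
                            impacts = x_impacts(), top_n = 10L,
                            n_perturbations = 256L, seed = 1L) {
  if (top_n < 1) stop_kgx("top_n must be >= 1", "kgx_validation_error")
  if (model$mode != "explanation") {
    stop_kgx("explanations require an explanation-mode model", "kgx_mode_error")
  }
  fg <- build_feature_graph(target, kg, mode = "explanation", index = index)
  score <- predict_score(model, fg)
  ec <- edge_contributions(model, fg, n_perturbations, seed)
  nc <- node_contributions(ec, fg)
  ntype <- fg$nodes$node_type
  names(ntype) <- fg$nodes$node_id
  ctx <- explain_context(fg)

  rows <- list()
  for (ri in seq_along(rules)) {
    rule <- rules[[ri]]
    for (m in rule$match(ctx)) {
      cb <- sentence_contribution(m$support, nc)
      sup <- intersect(m$support, names(nc))
      anchor <- if (length(sup)) sup[which.max(abs(nc[sup]))] else NA_character_
      imp <- if (is.na(anchor)) attr(impacts, "baseline") %||% 0.5 else {
        impact_of(impacts, unname(ntype[anchor]))
      }
      txt <- render_sentence(rule, m)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        rule = rule$name, rule_order = ri, text = txt,
        contribution = cb, impact = imp,
        x_factor = x_factor(cb, imp),
        support = list(m$support)
      )
    }
  }
  if (!length(rows)) {
    return(tibble::tibble(
      rank = integer(), rule = character(), text = character(),
      x_factor = numeric(), contribution = numeric(), impact = numeric(),
      score = numeric(), support = list()
    ))
  }
  out <- do.call(rbind, rows)
  o <- order(-out$x_factor, out$rule_order, out$text)
  out <- out[o, ][seq_len(min(top_n, nrow(out))), ]
  out$rank <- seq_len(nrow(out))
  out$score <- score
  out[, c("rank", "rule", "text", "x_factor", "contribution", "impact",
          "score", "support")]
}

#' Write explanations as text and TSV
#'
#' @param explanation result of [explain_variant()].
#' @param path output path; `.txt` gets one sentence per line, and a
#'   companion `.tsv` gets rank, x_factor, rule, text and support ids.
#' @return invisibly, `path`.
#' @export
write_explanation <- function(explanation, path) {
  writeLines(explanation$text, path)
  tsv <- sub("\\.txt$", "", path)
  out <- explanation
  out$support <- vapply(out$support, paste, character(1), collapse = ",")
  data.table::fwrite(
    out[, c("rank", "x_factor", "rule", "text", "support")],
    paste0(tsv, ".tsv"), sep = "\t"
  )
  invisible(path)
}
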