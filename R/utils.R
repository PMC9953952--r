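#' @importFrom stats plogis rbeta rbinom runif setNames predict aggregate
#' @importFrom utils head tail URLencode URLdecode
NULL

.datatable.aware <- TRUE

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Deterministic string hash
#'
#' Polynomial rolling hash over UTF-8 code points, reduced modulo `dim`.
#' Used to map edge tokens of a feature subgraph into a fixed-length
#' feature vector. Stable across platforms and R sessions.
#'
#' @param x character vector of tokens.
#' @param dim number of hash buckets.
#' @return integer vector of bucket indices in `1:dim`.
#' @keywords internal
hash_bucket <- function(x, dim = 512L) {
  vapply(x, function(s) {
    h <- 17
    for (cp in utf8ToInt(s)) h <- (h * 31 + cp) %% 2147483647
    as.integer(h %% dim) + 1L
  }, integer(1), USE.NAMES = FALSE)
}

# English words for 0..999, hyphenated tens, as used in rendered sentences.
num_to_words <- function(n) {
  stopifnot(is.numeric(n), n >= 0, n < 1000, n == floor(n))
  ones <- c(
    "zero", "one", "two", "three", "four", "five", "six", "seven", "eight",
    "nine", "ten", "eleven", "twelve", "thirteen", "fourteen", "fifteen",
    "sixteen", "seventeen", "eighteen", "nineteen"
  )
  tens <- c(
    "twenty", "thirty", "forty", "fifty", "sixty", "seventy", "eighty",
    "ninety"
  )
  word1 <- function(k) {
    if (k < 20) return(ones[k + 1])
    t <- tens[k %/% 10 - 1]
    r <- k %% 10
    if (r == 0) t else paste0(t, "-", ones[r + 1])
  }
  vapply(n, function(k) {
    if (k < 100) return(word1(k))
    h <- paste(ones[k %/% 100 + 1], "hundred")
    r <- k %% 100
    if (r == 0) h else paste(h, word1(r))
  }, character(1))
}

cap_first <- function(s) {
  paste0(toupper(substr(s, 1, 1)), substr(s, 2, nchar(s)))
}

# format a numeric payload so that round trips through character are exact
format_payload <- function(x) {
  if (is.character(x)) return(x)
  sprintf("%.17g", x)
}

# "missense_variant" -> "missense variant"
humanize_term <- function(x) gsub("_", " ", x, fixed = TRUE)

# evaluate code under a temporary RNG seed, restoring global RNG state
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, globalenv())
    else if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

stop_kgx <- function(msg, class) {
  stop(structure(
    class = c(class, "kgx_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}
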