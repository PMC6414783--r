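#' Round half away from zero
#'
#' Reporting convention for concordance rates: `round()` in R rounds half to
#' even, but table rates are conventionally rounded half-up (86.45 -> 86.5).
#' Full precision is always retained internally; this is applied only at the
#' reporting boundary.
#'
#' @param x numeric vector
#' @param digits number of decimal places
#' @return rounded numeric vector
#' @export
round_half_up <- function(x, digits = 1) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

# geometric mean; 0 if any element is 0 (log-mean convention used by
# median-of-ratios normalization, where such rows are excluded)
geom_mean <- function(x) {
  if (any(x <= 0)) return(0)
  exp(mean(log(x)))
}

DNA_BASES <- c("A", "C", "G", "T")

#' Reverse complement of a nucleotide string
#'
#' Accepts DNA or RNA alphabet (U is treated as T); N maps to N.
#'
#' @param x character scalar of nucleotides
#' @return character scalar
#' @export
revcomp <- function(x) {
  x <- normalize_dna(x)
  paste(rev(strsplit(chartr("ACGTN", "TGCAN", x), "")[[1]]), collapse = "")
}

# uppercase, RNA U -> DNA T; errors on anything outside {A,C,G,T,N}
normalize_dna <- function(x) {
  x <- chartr("u", "t", toupper(x))
  x <- chartr("U", "T", x)
  bad <- gsub("[ACGTN]", "", x)
  if (any(nchar(bad) > 0)) {
    stop("non-nucleotide characters in sequence: '",
         substr(bad[nchar(bad) > 0][1], 1, 1), "'")
  }
  x
}

complement_base <- function(b) chartr("ACGTN", "TGCAN", b)

# beta-binomial sampler parameterized by mean fraction and intraclass
# correlation rho; rho = 0 degenerates to pure binomial
rbetabinom <- function(n, size, prob, rho = 0) {
  stopifnot(rho >= 0, rho < 1)
  if (rho == 0) return(stats::rbinom(n, size, prob))
  a <- prob * (1 - rho) / rho
  b <- (1 - prob) * (1 - rho) / rho
  p <- stats::rbeta(n, a, b)
  stats::rbinom(n, size, p)
}

# check a probability-valued config field
check_prob <- function(value, name) {
  if (!is.numeric(value) || length(value) != 1 || is.na(value) ||
      value < 0 || value > 1) {
    stop("config field '", name, "' must be a probability in [0,1]")
  }
  invisible(value)
}

#' Stable hash of a configuration list
#'
#' md5 of the canonical (sorted-key) JSON serialization, so the hash changes
#' iff any parameter value changes.
#'
#' @param config a list of parameters
#' @return character md5 hash
#' @export
config_hash <- function(config) {
  strip <- function(x) if (is.list(x)) lapply(unclass(x), strip) else x
  config <- strip(config)
  config <- config[order(names(config))]
  js <- jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA, null = "null")
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  writeLines(as.character(js), tf)
  unname(tools::md5sum(tf))
}
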