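#' @importFrom stats median rbinom rlnorm runif setNames fisher.test
#' @importFrom utils read.delim write.table head tail
NULL

# Evaluate `expr` under a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

DNA_BASES <- c("A", "C", "G", "T")

# Normalize a nucleotide string: uppercase, RNA U -> T.
normalize_dna <- function(x) {
  chartr("u", "T", chartr("U", "T", toupper(x)))
}

check_dna <- function(x, allow_gap = FALSE, what = "sequence") {
  pat <- if (allow_gap) "^[ACGTN-]*$" else "^[ACGTN]*$"
  bad <- !grepl(pat, x)
  if (any(bad)) {
    stop(sprintf("%s contains characters outside {A,C,G,T,N%s}: %s",
                 what, if (allow_gap) ",-" else "",
                 paste(utils::head(names(x)[bad], 3), collapse = ", ")),
         call. = FALSE)
  }
  invisible(x)
}

#' Reverse complement of DNA strings
#'
#' @param x character vector of DNA strings (A/C/G/T/N).
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  vapply(x, function(s) {
    chartr("ACGTN", "TGCAN",
           paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = ""))
  }, character(1), USE.NAMES = FALSE)
}

# integer encoding A=0 C=1 G=2 T=3, anything else (N, mask) = 4
encode_dna <- function(s) {
  v <- utf8ToInt(s)
  out <- integer(length(v))
  out[] <- 4L
  out[v == utf8ToInt("A")] <- 0L
  out[v == utf8ToInt("C")] <- 1L
  out[v == utf8ToInt("G")] <- 2L
  out[v == utf8ToInt("T")] <- 3L
  out
}

decode_dna <- function(v) {
  paste(c(DNA_BASES, "N")[v + 1L], collapse = "")
}

random_dna <- function(n, base_comp = rep(0.25, 4)) {
  paste(sample(DNA_BASES, n, replace = TRUE, prob = base_comp), collapse = "")
}

ungap <- function(x) gsub("-", "", x, fixed = TRUE)
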