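#' Reverse complement of a DNA string
#' @param x Character scalar of DNA (ACGTN).
#' @return Reverse complement, uppercase.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(toupper(x))))
}

# Random DNA of length n using the session RNG stream.
random_dna <- function(n, bases = c("A", "C", "G", "T")) {
  paste(sample(bases, n, replace = TRUE), collapse = "")
}

# Apply iid point mutations at per-site rate to a DNA string.
mutate_dna <- function(seq, rate) {
  if (rate <= 0) return(seq)
  v <- strsplit(seq, "")[[1]]
  hit <- which(stats::runif(length(v)) < rate)
  for (i in hit) {
    v[i] <- sample(setdiff(c("A", "C", "G", "T"), v[i]), 1)
  }
  paste(v, collapse = "")
}

check_dna <- function(x, what = "sequence") {
  if (grepl("[^ACGTN]", x)) stop(what, " contains non-ACGTN characters")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# sample() treats a length-1 numeric as 1:n; this picks one element safely.
pick1 <- function(x) if (length(x) == 1) x else sample(x, 1)
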