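## Nei-Gojobori (1986) pairwise dN/dS with Jukes-Cantor correction and
## sliding-window selection-class calls.

.dd_cache <- new.env(parent = emptyenv())

genetic_code <- function() Biostrings::GENETIC_CODE

translate_codon <- function(codon) {
  aa <- genetic_code()[[codon]]
  if (is.null(aa)) stop("not a codon: ", codon)
  aa
}

is_stop <- function(codon) translate_codon(codon) == "*"

#' Synonymous and nonsynonymous site counts of one codon
#'
#' For each codon position, the three single-base alternatives are
#' enumerated against the standard genetic code; alternatives that create a
#' stop codon are excluded from the denominator (and the position's site
#' total renormalized so every codon contributes exactly 3 sites).
#'
#' @param codon Three-letter sense codon (ACGT).
#' @return Numeric vector `c(s_sites, n_sites)`, summing to 3.
#' @export
codon_sites <- function(codon) {
  codon <- toupper(codon)
  if (nchar(codon) != 3 || grepl("[^ACGT]", codon)) {
    stop("codon must be 3 ACGT bases: ", codon)
  }
  if (is_stop(codon)) stop("stop codon has no defined site counts: ", codon)
  key <- paste0("sites_", codon)
  hit <- .dd_cache[[key]]
  if (!is.null(hit)) return(hit)
  aa <- translate_codon(codon)
  s <- 0
  for (pos in 1:3) {
    alts <- setdiff(c("A", "C", "G", "T"), substr(codon, pos, pos))
    syn <- 0L; counted <- 0L
    for (b in alts) {
      mut <- codon
      substr(mut, pos, pos) <- b
      if (is_stop(mut)) next
      counted <- counted + 1L
      if (translate_codon(mut) == aa) syn <- syn + 1L
    }
    if (counted > 0) s <- s + syn / counted
  }
  out <- c(s_sites = s, n_sites = 3 - s)
  assign(key, out, envir = .dd_cache)
  out
}

#' Synonymous and nonsynonymous difference counts between two codons
#'
#' Averages synonymous/nonsynonymous step counts over all orderings of the
#' differing positions (Nei-Gojobori pathway averaging). Pathways passing
#' through stop codons are excluded and the average renormalized; when every
#' pathway passes through a stop, all pathways are used and the result is
#' flagged.
#'
#' @param codonA,codonB Sense codons.
#' @return Numeric vector `c(sd, nd)` with attribute `all_paths_stop`.
#' @export
codon_differences <- function(codonA, codonB) {
  codonA <- toupper(codonA); codonB <- toupper(codonB)
  if (is_stop(codonA) || is_stop(codonB)) stop("stop codon in comparison")
  diffpos <- which(strsplit(codonA, "")[[1]] != strsplit(codonB, "")[[1]])
  k <- length(diffpos)
  if (k == 0) {
    out <- c(sd = 0, nd = 0); attr(out, "all_paths_stop") <- FALSE
    return(out)
  }
  perms <- permutations(diffpos)
  path_sd <- numeric(0); path_nd <- numeric(0); through_stop <- logical(0)
  for (p in seq_len(nrow(perms))) {
    cur <- codonA; sd <- 0; nd <- 0; stopped <- FALSE
    for (pos in perms[p, ]) {
      nxt <- cur
      substr(nxt, pos, pos) <- substr(codonB, pos, pos)
      if (is_stop(nxt)) stopped <- TRUE
      else if (translate_codon(nxt) == translate_codon(cur)) sd <- sd + 1
      else nd <- nd + 1
      cur <- nxt
    }
    path_sd <- c(path_sd, sd); path_nd <- c(path_nd, nd)
    through_stop <- c(through_stop, stopped)
  }
  use <- !through_stop
  all_stop <- !any(use)
  if (all_stop) use <- rep(TRUE, length(use))
  out <- c(sd = mean(path_sd[use]), nd = mean(path_nd[use]))
  attr(out, "all_paths_stop") <- all_stop
  out
}

permutations <- function(x) {
  n <- length(x)
  if (n == 1) return(matrix(x, 1))
  out <- NULL
  for (i in seq_len(n)) {
    rest <- permutations(x[-i])
    out <- rbind(out, cbind(x[i], rest))
  }
  out
}

#' Jukes-Cantor multiple-hit correction
#'
#' `d = -(3/4) log(1 - 4p/3)`, defined for `0 <= p < 3/4`.
#'
#' @param p Proportion of differences.
#' @return Corrected distance `d >= p`.
#' @export
jukes_cantor <- function(p) {
  if (any(p < 0)) stop("p must be non-negative")
  if (any(p >= 0.75)) stop("Jukes-Cantor correction undefined for p >= 3/4 (saturation)")
  d <- -0.75 * log(1 - 4 * p / 3)
  d[p == 0] <- 0  # avoid negative zero
  d
}

split_codons <- function(cds) {
  cds <- toupper(cds)
  n <- nchar(cds)
  if (n %% 3 != 0) stop("CDS length not a multiple of 3")
  substring(cds, seq(1, n, 3), seq(3, n, 3))
}

#' Pairwise dN/dS by the Nei-Gojobori (1986) method
#'
#' Counts synonymous/nonsynonymous sites (averaged over the two sequences)
#' and differences (pathway-averaged), then applies the Jukes-Cantor
#' correction to pS and pN. Codons containing a gap, an ambiguous base, or a
#' stop in either sequence are dropped pairwise. `omega` is `NA` (undefined)
#' when `dS == 0`; `dS`/`dN` are `NA` with `saturated = TRUE` when the
#' corresponding p-distance reaches 3/4.
#'
#' @param cdsA,cdsB Equal-length in-frame aligned coding sequences
#'   (`-` allowed as gap).
#' @return Object of class `dnds_result`: list with `S`, `N`, `Sd`, `Nd`,
#'   `pS`, `pN`, `dS`, `dN`, `omega`, `n_codons` (compared), `saturated`.
#' @export
pairwise_dnds <- function(cdsA, cdsB) {
  if (nchar(cdsA) != nchar(cdsB)) stop("sequences must be aligned to equal length")
  ca <- split_codons(cdsA); cb <- split_codons(cdsB)
  ok <- !grepl("[^ACGT]", ca) & !grepl("[^ACGT]", cb)
  ok[ok] <- !vapply(ca[ok], is_stop, logical(1)) &
            !vapply(cb[ok], is_stop, logical(1))
  ca <- ca[ok]; cb <- cb[ok]
  if (length(ca) == 0) stop("no comparable codons after filtering")
  SA <- 0; SB <- 0; Sd <- 0; Nd <- 0
  for (i in seq_along(ca)) {
    SA <- SA + codon_sites(ca[i])[["s_sites"]]
    SB <- SB + codon_sites(cb[i])[["s_sites"]]
    d <- codon_differences(ca[i], cb[i])
    Sd <- Sd + d[["sd"]]; Nd <- Nd + d[["nd"]]
  }
  S <- (SA + SB) / 2
  N <- 3 * length(ca) - S
  pS <- Sd / S; pN <- Nd / N
  sat <- FALSE
  dS <- if (pS < 0.75) jukes_cantor(pS) else { sat <- TRUE; NA_real_ }
  dN <- if (pN < 0.75) jukes_cantor(pN) else { sat <- TRUE; NA_real_ }
  omega <- if (!is.na(dS) && !is.na(dN) && dS > 0) dN / dS else NA_real_
  structure(list(S = S, N = N, Sd = Sd, Nd = Nd, pS = pS, pN = pN,
                 dS = dS, dN = dN, omega = omega,
                 n_codons = length(ca), saturated = sat),
            class = "dnds_result")
}

#' @export
print.dnds_result <- function(x, ...) {
  cat(sprintf(
    "<dnds_result> %d codons  S=%.2f N=%.2f  Sd=%.2f Nd=%.2f  dS=%s dN=%s  omega=%s\n",
    x$n_codons, x$S, x$N, x$Sd, x$Nd,
    formatC(x$dS, digits = 4, format = "f"),
    formatC(x$dN, digits = 4, format = "f"),
    if (is.na(x$omega)) "undefined" else formatC(x$omega, digits = 3, format = "f")))
  invisible(x)
}

#' Selection class from a dN/dS ratio
#'
#' Thresholds follow the sliding-window heuristic used for duplicate-gene
#' scans: positive selection requires `omega > 1.5`, purifying selection
#' `omega < 0.67`; in between is intermediate. An undefined ratio (`NA`,
#' from `dS == 0` or saturation) is passed through as `"UNDEFINED"`.
#'
#' @param omega dN/dS ratio or `NA`.
#' @param positive,purifying Class thresholds.
#' @return One of `"POSITIVE"`, `"PURIFYING"`, `"INTERMEDIATE"`, `"UNDEFINED"`.
#' @export
classify_selection <- function(omega, positive = 1.5, purifying = 0.67) {
  if (length(omega) != 1) return(vapply(omega, classify_selection, character(1),
                                        positive = positive, purifying = purifying))
  if (is.na(omega)) return("UNDEFINED")
  if (omega < 0) stop("negative omega")
  if (omega > positive) "POSITIVE"
  else if (omega < purifying) "PURIFYING"
  else "INTERMEDIATE"
}

#' Sliding-window dN/dS scan of a codon alignment
#'
#' Windows of `window` codons advanced by `step` codons; each window is
#' scored with [pairwise_dnds()] and classified with [classify_selection()].
#' An alignment shorter than one window yields a single whole-sequence
#' window with a warning.
#'
#' @param cdsA,cdsB Aligned in-frame coding sequences.
#' @param window,step Window size and offset, in codons.
#' @param positive,purifying Classification thresholds.
#' @return Object of class `window_track`: data.frame with `start_codon`,
#'   `end_codon`, NG86 statistics, `omega` and `selection_class` per window.
#' @export
sliding_window <- function(cdsA, cdsB, window = 45L, step = 9L,
                           positive = 1.5, purifying = 0.67) {
  L <- nchar(cdsA) / 3
  if (L != floor(L)) stop("alignment length not a multiple of 3")
  if (L < window) {
    warning("alignment shorter than one window; returning whole-sequence result")
    starts <- 1L
    window <- as.integer(L)
  } else {
    n <- floor((L - window) / step) + 1
    starts <- 1L + (seq_len(n) - 1L) * step
  }
  rows <- lapply(starts, function(s) {
    a <- substr(cdsA, (s - 1) * 3 + 1, (s + window - 1) * 3)
    b <- substr(cdsB, (s - 1) * 3 + 1, (s + window - 1) * 3)
    r <- pairwise_dnds(a, b)
    data.frame(start_codon = s, end_codon = s + window - 1L,
               S = r$S, N = r$N, Sd = r$Sd, Nd = r$Nd,
               pS = r$pS, pN = r$pN, dS = r$dS, dN = r$dN,
               omega = r$omega,
               selection_class = classify_selection(r$omega, positive, purifying),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "window") <- window
  attr(out, "step") <- step
  class(out) <- c("window_track", "data.frame")
  out
}

#' N-terminal vs C-terminal selection summary of a window track
#'
#' N-terminal windows lie entirely within the first `nterm_codons` codons
#' (`end_codon <= nterm_codons`); C-terminal windows lie entirely within the
#' last `nterm_codons` codons. A single whole-sequence window can belong to
#' both groups.
#'
#' @param track A [sliding_window()] result.
#' @param nterm_codons Size of the terminal regions, in codons (default 50,
#'   the span of the family-defining N-terminal domain).
#' @return List with `nterm_max_omega`, `cterm_max_omega`,
#'   `cterm_positive` (any C-terminal window called POSITIVE) and
#'   `positive_windows` (start codons of all POSITIVE windows).
#' @export
nterm_cterm_summary <- function(track, nterm_codons = 50L) {
  if (nrow(track) == 0) stop("empty window track")
  L <- max(track$end_codon)
  ntm <- track$end_codon <= nterm_codons
  ctm <- track$start_codon > L - nterm_codons
  mx <- function(x) if (all(is.na(x))) NA_real_ else max(x, na.rm = TRUE)
  list(nterm_max_omega = mx(track$omega[ntm]),
       cterm_max_omega = mx(track$omega[ctm]),
       cterm_positive = any(track$selection_class[ctm] == "POSITIVE"),
       positive_windows = track$start_codon[track$selection_class == "POSITIVE"])
}
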