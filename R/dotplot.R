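## Self-comparison dot matrix and tandem-repeat detection.

#' Self dot matrix of a DNA sequence
#'
#' Compares every pair of `window`-length substrings at stride 1 and keeps
#' pairs (i, j), i < j, agreeing at `>= ceiling(window * min_identity)`
#' positions. Forward-strand direct-repeat comparison only; the self
#' diagonal is excluded and each unordered pair is stored once.
#'
#' @param seq DNA string, length `>= window`.
#' @param window Window length in bp (default 30).
#' @param min_identity Minimum fraction of agreeing positions (default 0.6).
#' @return Object of class `dot_matrix`: list with `matches` (data.frame
#'   `i`, `j`, `n_match`), `seq_len`, `window`, `min_identity`.
#' @export
self_dot_matrix <- function(seq, window = 30L, min_identity = 0.6) {
  seq <- toupper(seq)
  check_dna(seq)
  L <- nchar(seq)
  if (L < window) stop("sequence shorter than one window")
  need <- ceiling(window * min_identity)
  v <- strsplit(seq, "")[[1]]
  res_i <- integer(0); res_j <- integer(0); res_m <- integer(0)
  max_start <- L - window + 1L
  for (d in seq_len(L - window)) {
    n <- L - d                       # length of the overlap at offset d
    if (n < window) break
    eq <- v[seq_len(n)] == v[seq_len(n) + d]
    cs <- cumsum(eq)
    nw <- n - window + 1L            # window starts available at this offset
    wsum <- cs[window:n] - c(0L, cs[seq_len(nw - 1L)])
    hit <- which(wsum >= need)
    if (length(hit)) {
      res_i <- c(res_i, hit)
      res_j <- c(res_j, hit + d)
      res_m <- c(res_m, wsum[hit])
    }
  }
  structure(list(matches = data.frame(i = res_i, j = res_j, n_match = res_m),
                 seq_len = L, window = as.integer(window),
                 min_identity = min_identity),
            class = "dot_matrix")
}

#' @export
print.dot_matrix <- function(x, ...) {
  cat(sprintf("<dot_matrix> L=%d window=%d min_identity=%.2f  %d off-diagonal match(es)\n",
              x$seq_len, x$window, x$min_identity, nrow(x$matches)))
  invisible(x)
}

#' Call tandem repeats from a dot matrix
#'
#' Off-diagonal matches are chained into collinear runs (same offset within
#' `offset_tol`, adjacent window starts); a region supported by at least
#' `min_runs` runs whose offsets sit at near-multiples of a common unit
#' yields a repeat call, with the unit length estimated as the modal spacing
#' between the distinct run offsets.
#'
#' @param dm A [self_dot_matrix()] result.
#' @param offset_tol Offset tolerance when chaining (default 2).
#' @param min_run_len Minimum collinear windows per run (default 10; short
#'   spurious runs arise readily by chance at 60% identity).
#' @param min_runs Minimum runs per repeat region (default 2).
#' @return data.frame of class `repeat_calls`: `start`, `end`,
#'   `unit_length`, `n_runs`, `mean_offset` (one row per repeat region).
#' @export
call_repeats <- function(dm, offset_tol = 2L, min_run_len = 10L, min_runs = 2L) {
  empty <- data.frame(start = integer(0), end = integer(0),
                      unit_length = integer(0), n_runs = integer(0),
                      mean_offset = numeric(0))
  m <- dm$matches
  if (nrow(m) == 0) return(structure(empty, class = c("repeat_calls", "data.frame")))
  m$offset <- m$j - m$i
  m <- m[order(m$offset, m$i), ]
  # chain into runs: same offset (+/- tol) and consecutive window starts
  run_id <- integer(nrow(m)); rid <- 0L
  for (k in seq_len(nrow(m))) {
    if (k > 1 &&
        abs(m$offset[k] - m$offset[k - 1]) <= offset_tol &&
        m$i[k] - m$i[k - 1] == 1L) {
      run_id[k] <- rid
    } else {
      rid <- rid + 1L
      run_id[k] <- rid
    }
  }
  runs <- do.call(rbind, lapply(split(seq_len(nrow(m)), run_id), function(ix) {
    data.frame(i_start = min(m$i[ix]), i_end = max(m$i[ix]),
               j_end = max(m$j[ix]), offset = round(mean(m$offset[ix])),
               len = length(ix))
  }))
  runs <- runs[runs$len >= min_run_len, , drop = FALSE]
  if (nrow(runs) == 0) return(structure(empty, class = c("repeat_calls", "data.frame")))
  # group runs into regions by span overlap
  runs$span_start <- runs$i_start
  runs$span_end <- runs$j_end + dm$window - 1L
  runs <- runs[order(runs$span_start), , drop = FALSE]
  region <- integer(nrow(runs)); reg <- 1L
  region[1] <- reg; cur_end <- runs$span_end[1]
  for (k in seq_len(nrow(runs))[-1]) {
    if (runs$span_start[k] <= cur_end) {
      region[k] <- reg
      cur_end <- max(cur_end, runs$span_end[k])
    } else {
      reg <- reg + 1L
      region[k] <- reg
      cur_end <- runs$span_end[k]
    }
  }
  calls <- lapply(split(runs, region), function(r) {
    if (nrow(r) < min_runs) return(NULL)
    offs <- sort(unique(r$offset))
    spacing <- diff(c(0L, offs))
    tb <- table(spacing)
    unit <- as.integer(names(tb)[which.max(tb)])  # modal spacing
    # tandem repeats put every run offset at a near-multiple of the unit;
    # unrelated coincidental runs rarely satisfy this
    mult_ok <- abs(r$offset - round(r$offset / unit) * unit) <= offset_tol
    r <- r[mult_ok, , drop = FALSE]
    if (nrow(r) < min_runs) return(NULL)
    # the fundamental-offset runs (offset ~ unit) tile the whole repeat
    # region; higher multiples and coincidental near-multiple runs would
    # only inflate the span
    fund <- r[abs(r$offset - unit) <= offset_tol, , drop = FALSE]
    if (nrow(fund) == 0) fund <- r
    st <- min(fund$span_start); en <- max(fund$span_end)
    if (en - st < 2 * unit) return(NULL)
    data.frame(start = st, end = en, unit_length = unit,
               n_runs = nrow(r), mean_offset = mean(r$offset))
  })
  calls <- do.call(rbind, calls[!vapply(calls, is.null, logical(1))])
  if (is.null(calls)) calls <- empty
  rownames(calls) <- NULL
  structure(calls, class = c("repeat_calls", "data.frame"))
}

#' Repeat overlap per intron of a gene model
#'
#' @param gm A [gene_model()] (coordinates consistent with the sequence the
#'   dot matrix was computed on, i.e. span-local).
#' @param calls A [call_repeats()] result.
#' @return data.frame with one row per intron: `intron`, `start`, `end`,
#'   `length`, `repeat_bp`, `repeat_fraction`.
#' @export
annotate_introns <- function(gm, calls) {
  intr <- introns(gm)
  off <- gene_span(gm)[1] - 1L
  n <- nrow(intr)
  out <- data.frame(intron = seq_len(n),
                    start = intr[, 1], end = intr[, 2],
                    length = intr[, 2] - intr[, 1] + 1L,
                    repeat_bp = 0L, repeat_fraction = 0)
  if (n == 0 || nrow(calls) == 0) return(out)
  for (i in seq_len(n)) {
    a <- intr[i, 1] - off; b <- intr[i, 2] - off  # span-local intron coords
    ov <- pmax(0L, pmin(b, calls$end) - pmax(a, calls$start) + 1L)
    cov <- 0L
    if (any(ov > 0)) {
      # union of overlapping segments, not the sum (calls may overlap)
      segs <- cbind(pmax(a, calls$start), pmin(b, calls$end))
      segs <- segs[ov > 0, , drop = FALSE]
      segs <- segs[order(segs[, 1]), , drop = FALSE]
      cur_s <- segs[1, 1]; cur_e <- segs[1, 2]
      for (k in seq_len(nrow(segs))[-1]) {
        if (segs[k, 1] <= cur_e + 1L) cur_e <- max(cur_e, segs[k, 2])
        else { cov <- cov + (cur_e - cur_s + 1L); cur_s <- segs[k, 1]; cur_e <- segs[k, 2] }
      }
      cov <- cov + (cur_e - cur_s + 1L)
    }
    out$repeat_bp[i] <- cov
    out$repeat_fraction[i] <- cov / out$length[i]
  }
  out
}
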