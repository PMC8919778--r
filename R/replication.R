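#' Infer the replication terminus from the origin
#'
#' The terminus is placed half the replicon length from *ori* (floor for odd
#' lengths), modulo the length.
#'
#' @param ori 0-based origin coordinate.
#' @param length replicon length in nt.
#' @return 0-based terminus coordinate.
#' @export
infer_ter <- function(ori, length) {
  stopifnot(ori >= 0, ori < length)
  as.integer((ori + length %/% 2) %% length)
}

#' Replication model for one replicon
#'
#' @param replicon_id replicon identifier.
#' @param ori 0-based origin coordinate.
#' @param length replicon length.
#' @return list of class `ReplicationModel` (with inferred `ter`).
#' @export
replication_model <- function(replicon_id, ori, length) {
  structure(list(replicon_id = replicon_id, ori = as.integer(ori),
                 ter = infer_ter(ori, length), length = as.integer(length)),
            class = "ReplicationModel")
}

#' Leading/lagging strand classification
#'
#' Replichore 1 is the arc from *ori* to *ter* in ascending coordinates
#' (wrapping the origin when `ori > ter`); on it, the top (+) strand is the
#' leading strand, and lagging on replichore 2; the bottom (−) strand is
#' mirrored. Positions exactly at *ori* or *ter* are assigned to
#' replichore 1.
#'
#' @param position 0-based genome coordinate.
#' @param strand `"+"` or `"-"`.
#' @param model a [replication_model()].
#' @return `"leading"` or `"lagging"`.
#' @export
strand_class <- function(position, strand, model) {
  p <- position %% model$length
  in_rep1 <- if (model$ori <= model$ter) {
    (p >= model$ori & p < model$ter) | p == model$ter
  } else {
    p >= model$ori | p < model$ter | p == model$ter
  }
  if (in_rep1 == (strand == "+")) "leading" else "lagging"
}

#' Insertion bias score
#'
#' Ratio of the number of introns on the lagging strand to the number on the
#' leading strand. `ib >= 5` is a strong lagging-strand bias, `2 <= ib < 5`
#' moderate, otherwise weak/none; zero leading-strand introns with at least
#' one lagging gives `Inf` (strong), and no classified introns at all is
#' `undefined`.
#'
#' @param classes character vector of `"leading"`/`"lagging"` (one per call).
#' @return list of class `IBResult`: `n_lagging`, `n_leading`, `ib_score`,
#'   `category`.
#' @export
ib_score <- function(classes) {
  n_lag <- sum(classes == "lagging")
  n_lead <- sum(classes == "leading")
  if (n_lag + n_lead == 0) {
    ib <- NA_real_; cat <- "undefined"
  } else if (n_lead == 0) {
    ib <- Inf; cat <- "strong"
  } else {
    ib <- n_lag / n_lead
    cat <- if (ib >= 5) "strong" else if (ib >= 2) "moderate" else "weak/none"
  }
  structure(list(n_lagging = n_lag, n_leading = n_lead, ib_score = ib,
                 category = cat), class = "IBResult")
}

# Per-window G and C counts (N excluded by construction).
window_gc_counts <- function(seq, n_windows, wsize) {
  ch <- strsplit(substr(seq, 1L, n_windows * wsize), "")[[1]]
  gm <- matrix(ch == "G", nrow = wsize)
  cm <- matrix(ch == "C", nrow = wsize)
  list(G = colSums(gm), C = colSums(cm))
}

#' Windowed GC skew profile
#'
#' GC skew per window computed as (G − C)/(G + C), with N bases excluded
#' from the counts; windows with no G or C get skew 0 (flagged). A final
#' partial window is included when the length is not a multiple of
#' `window`; genomes shorter than one window fall back to a single window
#' with a warning. `cumulative` holds the running sum of the window skews.
#'
#' @param genome a `GenomeRecord`.
#' @param window window size in nt (default 10,000).
#' @return list of class `SkewProfile`: `window`, `skew`, `cumulative`,
#'   `empty_windows` (logical flag vector).
#' @export
gc_skew_profile <- function(genome, window = 10000L) {
  n <- genome$length
  if (n < window) {
    warning("genome shorter than one window; single-window fallback")
    window <- n
  }
  nfull <- n %/% window
  cnt <- window_gc_counts(genome$sequence, nfull, window)
  G <- cnt$G; C <- cnt$C
  if (n %% window > 0) {
    tailseq <- substr(genome$sequence, nfull * window + 1L, n)
    tch <- strsplit(tailseq, "")[[1]]
    G <- c(G, sum(tch == "G")); C <- c(C, sum(tch == "C"))
  }
  tot <- G + C
  empty <- tot == 0
  skew <- ifelse(empty, 0, (G - C) / ifelse(empty, 1, tot))
  structure(list(window = as.integer(window), skew = skew,
                 cumulative = cumsum(skew), empty_windows = empty),
            class = "SkewProfile")
}

#' GC skew index (GCSI)
#'
#' Strength of the genome-wide GC skew in `[0, 1]`: the replicon is split
#' into `n_windows` equal windows (trailing remainder dropped), per-window
#' skew is Fourier-transformed, and
#' `sr` = power at frequency 1 / mean power over all nonzero frequencies —
#' large when the skew flips sign exactly once around the replicon, as the
#' two-replichore structure predicts. `dist` = max − min of the cumulative
#' window skew. `gcsi = sqrt((sr / sr_norm) * (dist / dist_norm))`, clipped
#' to `[0, 1]`; the normalisation constants follow the generalized-GCSI
#' convention and are exposed as configuration.
#'
#' @param genome a `GenomeRecord` (length >= `n_windows`).
#' @param n_windows number of windows (default 4,096).
#' @param sr_norm,dist_norm normalisation constants (defaults 6,000 / 600).
#' @return list of class `GCSI`: `gcsi`, `sr`, `dist`, `skew` vector.
#' @export
gcsi <- function(genome, n_windows = 4096L, sr_norm = 6000, dist_norm = 600) {
  n <- genome$length
  stopifnot(n >= n_windows)
  wsize <- n %/% n_windows
  cnt <- window_gc_counts(genome$sequence, n_windows, wsize)
  tot <- cnt$G + cnt$C
  skew <- ifelse(tot == 0, 0, (cnt$G - cnt$C) / ifelse(tot == 0, 1, tot))
  sp <- Mod(stats::fft(skew))^2
  sr <- sp[2L] / mean(sp[-1L])
  # cumulative skew anchored at 0 so the amplitude is strand-symmetric
  cum <- c(0, cumsum(skew))
  dist <- max(cum) - min(cum)
  val <- sqrt((sr / sr_norm) * (dist / dist_norm))
  structure(list(gcsi = min(1, max(0, val)), sr = sr, dist = dist,
                 skew = skew), class = "GCSI")
}
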