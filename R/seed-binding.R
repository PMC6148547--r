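#' Seed-site scan of a 3'UTR
#'
#' Finds every offset at which the UTR carries the exact reverse complement
#' of miRNA positions 2-8 (1-based from the 5' end) - the 7-mer perfect
#' seed pairing rule. Overlapping matches are all reported. Coordinates are
#' 0-based half-open on the 5'-to-3' UTR strand; T is accepted and mapped
#' to U in both inputs.
#'
#' @param mirna miRNA sequence, length at least 8.
#' @param utr UTR sequence.
#' @param utr_id label carried into the output.
#' @return data.frame: `utr_id`, `start`, `end` (= start + 7), `site_seq`,
#'   `region` (fixed `"utr3"`), `au_fraction` of the 7-mer.
#' @export
seed_sites <- function(mirna, utr, utr_id = "utr") {
  mirna <- .as_rna(mirna, "miRNA")
  if (nchar(mirna) < 8) stop("miRNA shorter than 8 nt")
  utr <- .as_rna(utr, "UTR")
  site <- rna_revcomp(substr(mirna, 2, 8))
  starts <- .scan_sites(utr, site)
  data.frame(utr_id = rep(utr_id, length(starts)),
             start = starts, end = starts + 7L,
             site_seq = rep(site, length(starts)),
             region = rep("utr3", length(starts)),
             au_fraction = rep(au_fraction(site), length(starts)),
             stringsAsFactors = FALSE)
}

#' Seed-site scan over a set of UTRs
#'
#' @param mirna miRNA sequence.
#' @param utrs named character vector of UTR sequences.
#' @return row-bound [seed_sites()] tables.
#' @export
seed_sites_all <- function(mirna, utrs) {
  out <- do.call(rbind, lapply(names(utrs), function(id) {
    seed_sites(mirna, utrs[[id]], utr_id = id)
  }))
  if (is.null(out)) {
    out <- data.frame(utr_id = character(0), start = integer(0),
                      end = integer(0), site_seq = character(0),
                      region = character(0), au_fraction = numeric(0))
  }
  out
}

#' AU fraction of an RNA sequence
#'
#' @param seq non-empty RNA string (T accepted as U).
#' @return `(#A + #U) / length`.
#' @export
au_fraction <- function(seq) {
  seq <- .as_rna(seq)
  if (nchar(seq) == 0) stop("au_fraction needs a non-empty sequence")
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  mean(chars %in% c("A", "U"))
}

#' AU-rich-element classification of a UTR
#'
#' Scans AUUUA pentamers (overlapping occurrences included) and U-rich
#' windows (sliding windows of `window` nt with U fraction at least
#' `u_rich_frac`, merged into maximal intervals). Class II: an overlapping
#' AUUUA pair (offset difference below 5) within `near_nt` of a U-rich
#' window; class I: some AUUUA within `near_nt` of a U-rich window but no
#' such overlapping pair; class III: a U-rich window with no AUUUA at all;
#' otherwise none.
#'
#' @param utr RNA string, length at least `window`.
#' @param u_rich_frac U-fraction threshold for a U-rich window (default 0.8).
#' @param window sliding-window width in nt (default 10).
#' @param near_nt maximum motif-to-window gap in nt (default 20).
#' @param utr_id label carried into the output.
#' @return list: `utr_id`, `n_auuua`, `n_overlapping`, `u_rich_windows`
#'   (data.frame `start`, `end`, 0-based half-open), `are_class`
#'   (`"I"`, `"II"`, `"III"` or `"none"`).
#' @export
classify_are <- function(utr, u_rich_frac = 0.8, window = 10L, near_nt = 20L,
                         utr_id = "utr") {
  utr <- .as_rna(utr, "UTR")
  L <- nchar(utr)
  if (L < window) stop("UTR shorter than the scanning window")
  motif_starts <- .scan_sites(utr, "AUUUA")
  n_overlap_pairs <- 0L
  overlapping_starts <- integer(0)
  if (length(motif_starts) > 1) {
    d <- diff(motif_starts)
    n_overlap_pairs <- sum(d < 5)
    hit <- which(d < 5)
    overlapping_starts <- unique(c(motif_starts[hit], motif_starts[hit + 1]))
  }
  # sliding U-rich windows, merged into maximal intervals
  chars <- strsplit(utr, "", fixed = TRUE)[[1]] == "U"
  csum <- c(0, cumsum(chars))
  starts0 <- 0:(L - window)
  ufrac <- (csum[starts0 + window + 1] - csum[starts0 + 1]) / window
  rich <- starts0[ufrac >= u_rich_frac]
  u_windows <- data.frame(start = integer(0), end = integer(0))
  if (length(rich)) {
    breaks <- c(0, which(diff(rich) > 1), length(rich))
    u_windows <- do.call(rbind, lapply(seq_len(length(breaks) - 1), function(i) {
      grp <- rich[(breaks[i] + 1):breaks[i + 1]]
      data.frame(start = grp[1], end = grp[length(grp)] + window)
    }))
  }
  near_window <- function(st) {
    if (nrow(u_windows) == 0) return(FALSE)
    any(st + 5L + near_nt >= u_windows$start & st - near_nt <= u_windows$end)
  }
  class <- "none"
  if (nrow(u_windows) > 0) {
    if (n_overlap_pairs > 0 && any(vapply(overlapping_starts, near_window, logical(1)))) {
      class <- "II"
    } else if (length(motif_starts) > 0 &&
               any(vapply(motif_starts, near_window, logical(1)))) {
      class <- "I"
    } else if (length(motif_starts) == 0) {
      class <- "III"
    }
  }
  list(utr_id = utr_id, n_auuua = length(motif_starts),
       n_overlapping = n_overlap_pairs, u_rich_windows = u_windows,
       are_class = class)
}
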