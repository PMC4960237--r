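#' Kyte-Doolittle hydropathy scale
#'
#' Per-residue hydropathy values; `X` (unknown residue) scores 0.
#'
#' @format Named numeric vector over the 20 residues plus `X`.
#' @export
KYTE_DOOLITTLE <- c(A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5,
                    Q = -3.5, E = -3.5, G = -0.4, H = -3.2, I = 4.5,
                    L = 3.8, K = -3.9, M = 1.9, F = 2.8, P = -1.6,
                    S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V = 4.2,
                    X = 0)

#' PEP-CTERM scanner configuration
#'
#' Parameters of the heuristic C-terminal sorting-signal scanner: a literal
#' Pro-Glu-Pro motif in the C-terminal search region, followed (within a
#' small gap) by a hydrophobic transmembrane segment, followed by a cluster
#' of basic residues before the C-terminus. Defaults follow standard
#' sliding-window TM-prediction practice (window 11, Kyte-Doolittle
#' threshold 1.6, helix length 15-25 residues).
#'
#' @param window Odd sliding-window width for hydropathy (residues).
#' @param hydropathy_threshold Mean-window hydropathy calling a TM position.
#' @param tm_min_len,tm_max_len Accepted TM segment length range (residues).
#' @param tm_slack Residues of slack allowed above `tm_max_len`.
#' @param merge_gap Sub-threshold positions bridged when merging TM runs.
#' @param search_region C-terminal region (residues) searched for the motif.
#' @param motif_gap Max residues between motif end and TM segment start.
#' @param min_basic Minimum count of K/R after the TM segment.
#' @param basic_window Residues after the TM segment searched for basics.
#' @param min_length Minimum protein length scanned.
#' @param scale Hydropathy scale (named numeric; pluggable).
#' @return Object of class `pepcterm_config`.
#' @export
pepcterm_config <- function(window = 11, hydropathy_threshold = 1.6,
                            tm_min_len = 15, tm_max_len = 25, tm_slack = 5,
                            merge_gap = 2, search_region = 35, motif_gap = 5,
                            min_basic = 2, basic_window = 10, min_length = 60,
                            scale = KYTE_DOOLITTLE) {
  if (window %% 2 != 1 || window < 3) om_stop("window must be odd and >= 3")
  if (tm_min_len > tm_max_len) om_stop("tm_min_len exceeds tm_max_len")
  structure(list(window = window,
                 hydropathy_threshold = hydropathy_threshold,
                 tm_min_len = tm_min_len, tm_max_len = tm_max_len,
                 tm_slack = tm_slack, merge_gap = merge_gap,
                 search_region = search_region, motif_gap = motif_gap,
                 min_basic = min_basic, basic_window = basic_window,
                 min_length = min_length, scale = scale),
            class = "pepcterm_config")
}

as_pepcterm_config <- function(cfg) {
  if (inherits(cfg, "pepcterm_config")) return(cfg)
  if (is.null(cfg$scale)) cfg$scale <- KYTE_DOOLITTLE
  do.call(pepcterm_config, cfg)
}

#' Sliding-window hydropathy profile
#'
#' Mean hydropathy over a centered window of odd width; positions without a
#' full window are undefined, so the profile has `length(seq) - window + 1`
#' values, value `i` covering residues `i .. i + window - 1`.
#'
#' @param seq Amino-acid string (20 residues + X).
#' @param window Odd window width, at most the sequence length.
#' @param scale Named hydropathy scale (default Kyte-Doolittle).
#' @param protein_id Optional id attached to the profile.
#' @return List with `protein_id`, `window`, `values`.
#' @export
hydropathy_profile <- function(seq, window = 11, scale = KYTE_DOOLITTLE,
                               protein_id = NA_character_) {
  res <- strsplit(toupper(seq), "")[[1]]
  if (window %% 2 != 1) om_stop("window must be odd")
  if (window > length(res))
    om_stop("window (%d) exceeds sequence length (%d)", window, length(res))
  h <- scale[res]
  if (anyNA(h))
    om_stop("residue(s) outside the hydropathy scale: %s",
            paste(unique(res[is.na(h)]), collapse = ", "))
  cs <- c(0, cumsum(h))
  n <- length(res) - window + 1
  vals <- (cs[(window + 1):(length(res) + 1)] - cs[1:n]) / window
  list(protein_id = protein_id, window = window, values = unname(vals))
}

#' Find transmembrane segments in a hydropathy profile
#'
#' Maximal runs of window positions at or above the threshold are merged
#' when separated by at most `merge_gap` sub-threshold positions, expanded
#' outward over contiguous residues whose raw scale value is itself at or
#' above the threshold (window smoothing otherwise erodes the ends of a
#' genuine hydrophobic stretch), and reported when the resulting residue
#' span lies within `[min_len, max_len + slack]`.
#'
#' @param profile Output of [hydropathy_profile()].
#' @param seq The sequence the profile was computed from (for expansion).
#' @param threshold Window-mean hydropathy threshold (default 1.6).
#' @param min_len,max_len Accepted residue span (defaults 15, 25).
#' @param slack Extra residues tolerated above `max_len` (default 5).
#' @param merge_gap Sub-threshold positions bridged (default 2).
#' @param scale Hydropathy scale used for expansion.
#' @return `data.frame` with 0-based half-open `start`, `end` columns and
#'   `score` (mean raw hydropathy over the span), one row per segment.
#' @export
find_tm_segment <- function(profile, seq, threshold = 1.6, min_len = 15,
                            max_len = 25, slack = 5, merge_gap = 2,
                            scale = KYTE_DOOLITTLE) {
  v <- profile$values
  w <- profile$window
  hw <- (w - 1) %/% 2
  res <- strsplit(toupper(seq), "")[[1]]
  h <- unname(scale[res])
  above <- v >= threshold
  runs <- rle_runs(above)
  if (nrow(runs) == 0)
    return(data.frame(start = integer(), end = integer(), score = numeric()))
  # merge runs separated by <= merge_gap sub-threshold positions
  merged <- runs[1, , drop = FALSE]
  if (nrow(runs) > 1) for (k in 2:nrow(runs)) {
    last <- nrow(merged)
    if (runs$first[k] - merged$last[last] - 1 <= merge_gap)
      merged$last[last] <- runs$last[k]
    else merged <- rbind(merged, runs[k, ])
  }
  out <- lapply(seq_len(nrow(merged)), function(k) {
    # window positions -> residue centers (1-based), then covered residues
    s <- merged$first[k] + hw   # center of first above-threshold window
    e <- merged$last[k] + hw
    # expand over contiguous hydrophobic residues
    while (s > 1 && h[s - 1] >= threshold) s <- s - 1
    while (e < length(h) && h[e + 1] >= threshold) e <- e + 1
    len <- e - s + 1
    if (len < min_len || len > max_len + slack) return(NULL)
    data.frame(start = s - 1L, end = e, score = mean(h[s:e]))
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    data.frame(start = integer(), end = integer(), score = numeric())
  else out
}

# internal: first/last indices of TRUE runs
rle_runs <- function(x) {
  r <- rle(x)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  data.frame(first = starts[r$values], last = ends[r$values])
}

#' Scan one protein for a PEP-CTERM sorting signal
#'
#' A hit requires, within the C-terminal search region: the literal motif
#' `PEP`; a TM segment beginning no more than `motif_gap` residues after the
#' motif (the reported interval is clipped to start after the motif, since
#' window smoothing can extend a segment's apparent start into it); and at
#' least `min_basic` K/R residues within `basic_window` residues after the
#' TM segment. The leftmost qualifying motif wins ties. Absence of a signal
#' is not an error.
#'
#' @param record One-row protein record (`protein_id`, `sequence`) or a
#'   single sequence string.
#' @param cfg A [pepcterm_config()].
#' @return One-row `data.frame` hit (`protein_id`, `pep_start`, `tm_start`,
#'   `tm_end`, `basic_start`, `basic_end`, `n_basic`, `score`; 0-based
#'   half-open coordinates) or `NULL`. `score` is the mean TM hydropathy.
#' @export
scan_pep_cterm <- function(record, cfg = pepcterm_config()) {
  cfg <- as_pepcterm_config(cfg)
  if (is.character(record))
    record <- data.frame(protein_id = NA_character_, sequence = record,
                         stringsAsFactors = FALSE)
  seq <- toupper(record$sequence[1])
  L <- nchar(seq)
  if (L < cfg$min_length) return(NULL)
  region_start0 <- L - cfg$search_region      # 0-based region start
  peps <- gregexpr("PEP", seq, fixed = TRUE)[[1]]
  if (peps[1] == -1) return(NULL)
  peps0 <- peps - 1                           # 0-based motif starts
  peps0 <- peps0[peps0 >= region_start0]
  if (length(peps0) == 0) return(NULL)
  prof <- hydropathy_profile(seq, window = cfg$window, scale = cfg$scale,
                             protein_id = record$protein_id[1])
  tms <- find_tm_segment(prof, seq, threshold = cfg$hydropathy_threshold,
                         min_len = cfg$tm_min_len, max_len = cfg$tm_max_len,
                         slack = cfg$tm_slack, merge_gap = cfg$merge_gap,
                         scale = cfg$scale)
  if (nrow(tms) == 0) return(NULL)
  res <- strsplit(seq, "")[[1]]
  for (p0 in sort(peps0)) {                   # leftmost qualifying PEP wins
    motif_end0 <- p0 + 3
    for (k in seq_len(nrow(tms))) {
      tm_s <- max(tms$start[k], motif_end0)   # clip into the post-motif space
      tm_e <- tms$end[k]
      if (tm_s > motif_end0 + cfg$motif_gap) next
      if (tm_e <= tm_s) next
      if (tm_e - tm_s < cfg$tm_min_len) next  # clipped span must still qualify
      b_s <- tm_e
      b_e <- min(tm_e + cfg$basic_window, L)
      if (b_e <= b_s) next
      n_basic <- sum(res[(b_s + 1):b_e] %in% c("K", "R"))
      if (n_basic < cfg$min_basic) next
      return(data.frame(protein_id = record$protein_id[1],
                        pep_start = p0, tm_start = tm_s, tm_end = tm_e,
                        basic_start = b_s, basic_end = b_e,
                        n_basic = n_basic,
                        score = mean(KD_scores(res, cfg$scale)[(tm_s + 1):tm_e]),
                        stringsAsFactors = FALSE))
    }
  }
  NULL
}

KD_scores <- function(res, scale) unname(scale[res])

#' Scan a proteome for PEP-CTERM proteins
#'
#' @param records Protein records data.frame ([read_fasta()] output).
#' @param cfg A [pepcterm_config()].
#' @return `data.frame` of hits (possibly zero rows), one row per hit
#'   protein, same columns as [scan_pep_cterm()].
#' @export
scan_proteome <- function(records, cfg = pepcterm_config()) {
  hits <- lapply(seq_len(nrow(records)),
                 function(i) scan_pep_cterm(records[i, , drop = FALSE], cfg))
  hits <- do.call(rbind, hits)
  if (is.null(hits))
    hits <- data.frame(protein_id = character(), pep_start = integer(),
                       tm_start = integer(), tm_end = integer(),
                       basic_start = integer(), basic_end = integer(),
                       n_basic = integer(), score = numeric(),
                       stringsAsFactors = FALSE)
  pipeline_log("PEP-CTERM scan: %d hit(s) in %d protein(s)",
               nrow(hits), nrow(records))
  hits
}

#' Write PEP-CTERM hits as GFF3
#'
#' Features typed `PEP_CTERM_sorting_signal` with `pep_motif`,
#' `transmembrane_segment` and `basic_cluster` subfeatures; coordinates are
#' converted from the internal 0-based half-open convention to GFF3's
#' 1-based closed intervals. Written with [rtracklayer::export()].
#'
#' @param hits Hit table from [scan_proteome()].
#' @param path Output `.gff3` path.
#' @return Invisibly, `path`.
#' @export
write_pepcterm_gff3 <- function(hits, path) {
  if (nrow(hits) == 0) {
    writeLines("##gff-version 3", path)
    return(invisible(path))
  }
  parent_id <- paste0("pepcterm_", hits$protein_id)
  mk <- function(start0, end0, type, id, parent = NA_character_) {
    gr <- GenomicRanges::GRanges(
      seqnames = hits$protein_id,
      ranges = IRanges::IRanges(start = start0 + 1L, end = end0))
    gr$source <- "omprofiler"
    gr$type <- type
    gr$ID <- id
    gr$Parent <- parent
    gr
  }
  full <- mk(hits$pep_start, hits$basic_end, "PEP_CTERM_sorting_signal",
             parent_id)
  motif <- mk(hits$pep_start, hits$pep_start + 3L, "pep_motif",
              paste0(parent_id, ".motif"), parent_id)
  tm <- mk(hits$tm_start, hits$tm_end, "transmembrane_segment",
           paste0(parent_id, ".tm"), parent_id)
  basic <- mk(hits$basic_start, hits$basic_end, "basic_cluster",
              paste0(parent_id, ".basic"), parent_id)
  gr <- c(full, motif, tm, basic)
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}
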