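#' Strand-specific coverage tracks
#'
#' Container for per-position read coverage of the two mtDNA strands.
#'
#' @param fwd,rev Non-negative numeric vectors of per-position coverage
#'   (equal length) for the forward and reverse strand.
#' @param circular Logical topology flag.
#' @return An object of class `coverage_track`.
#' @export
coverage_track <- function(fwd, rev, circular = TRUE) {
  stopifnot(length(fwd) == length(rev), all(fwd >= 0), all(rev >= 0))
  structure(list(length = length(fwd), fwd = as.numeric(fwd),
                 rev = as.numeric(rev), circular = isTRUE(circular)),
            class = "coverage_track")
}

#' @export
print.coverage_track <- function(x, ...) {
  cat(sprintf("<coverage_track: %d bp, %s; mean fwd %.2f, rev %.2f>\n",
              x$length, if (x$circular) "circular" else "linear",
              mean(x$fwd), mean(x$rev)))
  invisible(x)
}

#' Prepend the circular tail of a coverage track
#'
#' Reads spanning the arbitrary position 1 of a circular molecule are
#' lost when the genome is treated linearly; prepending the last
#' `prepend` positions restores coverage continuity across the origin.
#' The returned object carries a `remap()` closure translating extended
#' coordinates (1-based) back to original ones.
#'
#' @param track A [coverage_track()].
#' @param prepend Number of terminal positions to prepend (default 500).
#' @return List with `track` (the extended `coverage_track`, flagged
#'   linear) and `remap` (function from extended to original 1-based
#'   positions).
#' @export
extend_circular <- function(track, prepend = 500) {
  if (!track$circular) {
    warning("linear track: extend_circular is the identity")
    return(list(track = track, remap = identity))
  }
  L <- track$length
  stopifnot(prepend < L)
  idx <- c(seq(L - prepend + 1, L), seq_len(L))
  ext <- coverage_track(track$fwd[idx], track$rev[idx], circular = FALSE)
  remap <- function(pos) ((pos - prepend - 1) %% L) + 1
  list(track = ext, remap = remap)
}

# Strand-oriented circular window means around every position.
# For the forward strand, "upstream" of position i means lower
# coordinates; on the reverse strand the orientation flips.
window_means <- function(cov, us_len, ds_len, downstream_increasing,
                         circular) {
  n <- length(cov)
  pad <- max(us_len, ds_len)
  if (circular) {
    ext <- c(tail(cov, pad), cov, head(cov, pad))
  } else {
    ext <- c(rep(NA_real_, pad), cov, rep(NA_real_, pad))
  }
  cs <- cumsum(c(0, ifelse(is.na(ext), 0, ext)))
  nas <- cumsum(c(0, is.na(ext)))
  wmean <- function(from, len) {
    # mean of ext[from .. from+len-1] (vectorized over from); NA if any
    # position missing (linear-genome edge)
    s <- cs[from + len] - cs[from]
    bad <- (nas[from + len] - nas[from]) > 0
    ifelse(bad, NA_real_, s / len)
  }
  i <- seq_len(n) + pad  # positions in ext coordinates
  if (downstream_increasing) {
    us <- wmean(i - us_len, us_len)
    ds <- wmean(i, ds_len)
  } else {
    us <- wmean(i + 1, us_len)
    ds <- wmean(i - ds_len + 1, ds_len)
  }
  comb <- (us * us_len + ds * ds_len) / (us_len + ds_len)
  list(us = us, ds = ds, comb = comb)
}

#' Scan a coverage track for TIS/TTS candidate positions
#'
#' Position `i` is a TIS candidate when the 200-bp upstream window mean
#' falls below `sf` times the combined 700-bp window mean while the
#' 500-bp downstream window mean exceeds the combined mean; a TTS
#' candidate satisfies the mirrored condition.  The scaling factor `sf`
#' multiplies the low side of the step, so a smaller `sf` is stricter.
#' "Downstream" follows the strand: increasing coordinates on the
#' forward strand, decreasing on the reverse.  On circular tracks the
#' windows wrap; on linear tracks positions lacking a full window are
#' skipped.
#'
#' @param track A [coverage_track()].
#' @param strand `"+"` or `"-"`.
#' @param sf Scaling factor in (0, 1].
#' @param us_len,ds_len Scan window lengths (defaults 200 and 500 bp).
#' @return Data frame of candidates: `kind` (`TIS`/`TTS`), `strand`,
#'   `pos` (1-based), `coverage` (at `pos`).
#' @export
scan_sites <- function(track, strand = c("+", "-"), sf,
                       us_len = 200, ds_len = 500) {
  strand <- match.arg(strand)
  stopifnot(sf > 0, sf <= 1)
  cov <- if (strand == "+") track$fwd else track$rev
  wm <- window_means(cov, us_len, ds_len,
                     downstream_increasing = strand == "+",
                     circular = track$circular)
  ok <- !is.na(wm$comb) & wm$comb > 0
  tis <- ok & wm$us < sf * wm$comb & wm$ds > wm$comb
  tts <- ok & wm$ds < sf * wm$comb & wm$us > wm$comb
  pos <- seq_len(track$length)
  out <- rbind(
    if (any(tis)) data.frame(kind = "TIS", strand = strand,
                             pos = pos[tis], coverage = cov[tis]),
    if (any(tts)) data.frame(kind = "TTS", strand = strand,
                             pos = pos[tts], coverage = cov[tts]))
  if (is.null(out)) {
    out <- data.frame(kind = character(), strand = character(),
                      pos = integer(), coverage = numeric())
  }
  out
}

#' Optimize the scan scaling factor for a sample
#'
#' Walks the grid 0.9, 0.85, ..., 0.05 and returns the smallest value
#' at which [scan_sites()] still yields candidates — the strictest
#' setting that permits detection.  Candidate sets are nested along the
#' grid (smaller `sf` is strictly harder to satisfy), so this is the
#' grid value immediately above the first all-empty one.  If even 0.9
#' yields nothing, 0.9 is returned with `no_sites = TRUE`.  Peaks
#' (TIS) and valleys (TTS) are separate detection problems with
#' different sensitivity on a noisy baseline, so the factor can be
#' optimized for one `kind` at a time (the default optimizes jointly).
#'
#' @inheritParams scan_sites
#' @param grid Descending grid of scaling factors.
#' @param kind Optimize for `"TIS"` candidates, `"TTS"` candidates, or
#'   `"any"`.
#' @return List `sf`, `no_sites`.
#' @export
optimize_sf <- function(track, strand = c("+", "-"),
                        grid = seq(0.9, 0.05, by = -0.05),
                        us_len = 200, ds_len = 500,
                        kind = c("any", "TIS", "TTS")) {
  strand <- match.arg(strand)
  kind <- match.arg(kind)
  grid <- sort(grid)  # ascend: first non-empty is the minimum
  for (sf in grid) {
    cand <- scan_sites(track, strand, sf, us_len = us_len,
                       ds_len = ds_len)
    if (kind != "any") cand <- cand[cand$kind == kind, , drop = FALSE]
    if (nrow(cand) > 0) return(list(sf = sf, no_sites = FALSE))
  }
  list(sf = max(grid), no_sites = TRUE)
}

# Position-specific confidence score: avg_ds / (avg_ds + avg_us) for a
# TIS and its complement for a TTS (250-bp downstream and 50-bp
# upstream windows).  1 means a perfectly sharp initiation (zero
# upstream coverage) or termination (zero downstream coverage).
confidence_score <- function(track, strand, pos, kind,
                             ds_len = 250, us_len = 50) {
  cov <- if (strand == "+") track$fwd else track$rev
  wm <- window_means(cov, us_len, ds_len,
                     downstream_increasing = strand == "+",
                     circular = track$circular)
  us <- wm$us[pos]; ds <- wm$ds[pos]
  denom <- us + ds
  score <- ifelse(is.na(denom) | denom == 0, NA_real_, ds / denom)
  ifelse(kind == "TIS", score, 1 - score)
}

#' Aggregate nearby candidates into representative sites
#'
#' Chains candidates of one kind and strand that lie within `radius`
#' bases of each other into a single aggregate and keeps one
#' representative: the position of maximum coverage for TIS (peak)
#' aggregates, minimum coverage for TTS (valley) aggregates (earliest
#' position in strand orientation on ties).  The confidence score is
#' recomputed at the representative; aggregates with an undefined score
#' (zero coverage in both confidence windows) are discarded.
#'
#' @param candidates Output of [scan_sites()].
#' @param track The [coverage_track()] the candidates came from.
#' @param radius Chaining radius in bases (default 100).
#' @return Data frame `kind`, `strand`, `pos`, `score`, `n_candidates`.
#' @export
aggregate_local <- function(candidates, track, radius = 100) {
  if (nrow(candidates) == 0) {
    return(data.frame(kind = character(), strand = character(),
                      pos = integer(), score = numeric(),
                      n_candidates = integer()))
  }
  rows <- lapply(split(candidates,
                       paste(candidates$kind, candidates$strand)),
                 function(d) {
    d <- d[order(d$pos), ]
    cl <- cumsum(c(1, diff(d$pos) > radius))
    lapply(split(d, cl), function(g) {
      ord <- if (g$strand[1] == "+") order(g$pos) else order(-g$pos)
      g <- g[ord, ]
      rep_pos <- if (g$kind[1] == "TIS") {
        g$pos[which.max(g$coverage)]
      } else {
        g$pos[which.min(g$coverage)]
      }
      data.frame(kind = g$kind[1], strand = g$strand[1], pos = rep_pos,
                 score = confidence_score(track, g$strand[1], rep_pos,
                                          g$kind[1]),
                 n_candidates = nrow(g))
    })
  })
  out <- do.call(rbind, unlist(rows, recursive = FALSE))
  out <- out[!is.na(out$score), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Detect TIS/TTS sites on both strands of a sample
#'
#' Convenience wrapper: per strand and site kind, optimizes the scaling
#' factor, scans, and aggregates local candidates.
#'
#' @param track A [coverage_track()].
#' @param radius Aggregation radius (default 100 bp).
#' @inheritParams optimize_sf
#' @return Data frame of sites with an `sf` column recording the factor
#'   used for that strand and kind.
#' @export
detect_sites <- function(track, grid = seq(0.9, 0.05, by = -0.05),
                         radius = 100, us_len = 200, ds_len = 500) {
  combos <- expand.grid(st = c("+", "-"), kd = c("TIS", "TTS"),
                        stringsAsFactors = FALSE)
  out <- lapply(seq_len(nrow(combos)), function(i) {
    st <- combos$st[i]; kd <- combos$kd[i]
    opt <- optimize_sf(track, st, grid = grid, us_len = us_len,
                       ds_len = ds_len, kind = kd)
    if (opt$no_sites) return(NULL)
    cand <- scan_sites(track, st, opt$sf, us_len = us_len,
                       ds_len = ds_len)
    cand <- cand[cand$kind == kd, , drop = FALSE]
    agg <- aggregate_local(cand, track, radius = radius)
    if (nrow(agg)) agg$sf <- opt$sf
    agg
  })
  out <- do.call(rbind, out)
  if (is.null(out)) {
    out <- data.frame(kind = character(), strand = character(),
                      pos = integer(), score = numeric(),
                      n_candidates = integer(), sf = numeric())
  }
  rownames(out) <- NULL
  out
}

#' Merge site calls across samples
#'
#' Sites of the same kind and strand lying within `radius` bases of
#' each other across samples collapse into one consensus site at the
#' confidence-score-weighted average position; the consensus confidence
#' is the mean of the member scores.
#'
#' @param site_lists List of per-sample site tables (as from
#'   [detect_sites()]).
#' @param radius Merge radius in bases (default 100).
#' @return Data frame `kind`, `strand`, `pos`, `score`, `n_samples`.
#' @export
merge_across_samples <- function(site_lists, radius = 100) {
  all <- do.call(rbind, lapply(seq_along(site_lists), function(i) {
    d <- site_lists[[i]]
    if (is.null(d) || nrow(d) == 0) return(NULL)
    d$sample_index <- i
    d[, c("kind", "strand", "pos", "score", "sample_index")]
  }))
  if (is.null(all)) {
    return(data.frame(kind = character(), strand = character(),
                      pos = numeric(), score = numeric(),
                      n_samples = integer()))
  }
  rows <- lapply(split(all, paste(all$kind, all$strand)), function(d) {
    d <- d[order(d$pos), ]
    cl <- cumsum(c(1, diff(d$pos) > radius))
    lapply(split(d, cl), function(g) {
      w <- g$score
      pos <- if (sum(w) > 0) weighted.mean(g$pos, w) else mean(g$pos)
      data.frame(kind = g$kind[1], strand = g$strand[1], pos = pos,
                 score = mean(g$score),
                 n_samples = length(unique(g$sample_index)))
    })
  })
  out <- do.call(rbind, unlist(rows, recursive = FALSE))
  rownames(out) <- NULL
  out
}
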