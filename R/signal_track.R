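#' Strand-specific base-resolution signal track
#'
#' A `signal_track` holds PRO-seq 3' end counts as a sparse map from
#' (chromosome, strand, 0-based position) to a non-negative integer count.
#' Every coordinate in the package is 0-based half-open; a bedGraph line
#' `chrom s e v` contributes count `v` at each position in `[s, e)`.
#'
#' Internally the track keeps, per (chromosome, strand), a sorted position
#' vector and a cumulative count vector so that window sums are O(log n)
#' binary searches rather than scans.
#'
#' @param chrom character vector of chromosome names.
#' @param strand character vector of strands, "+" or "-".
#' @param pos integer vector of 0-based positions.
#' @param count integer vector of positive counts.
#' @param chrom_sizes optional named integer vector of chromosome lengths,
#'   used to validate positions and clip windows.
#' @return An object of class `signal_track`.
#' @export
signal_track <- function(chrom = character(), strand = character(),
                         pos = integer(), count = integer(),
                         chrom_sizes = NULL) {
  n <- length(pos)
  stopifnot(length(chrom) == n, length(strand) == n, length(count) == n)
  if (n > 0) {
    if (!all(strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
    if (any(count < 0)) stop("counts must be non-negative")
    if (any(pos < 0)) stop("positions must be >= 0")
  }
  dt <- data.table::data.table(chrom = as.character(chrom),
                               strand = as.character(strand),
                               pos = as.integer(pos),
                               count = as.numeric(count))
  dt <- dt[count > 0]
  if (nrow(dt) > 0) {
    dt <- dt[, list(count = sum(count)), by = c("chrom", "strand", "pos")]
  }
  data.table::setkeyv(dt, c("chrom", "strand", "pos"))
  if (!is.null(chrom_sizes) && nrow(dt) > 0) {
    bad <- dt$pos >= chrom_sizes[dt$chrom]
    if (any(is.na(bad)) || any(bad)) {
      stop("positions beyond chromosome length (or unknown chromosome)")
    }
  }
  idx <- new.env(parent = emptyenv())
  if (nrow(dt) > 0) {
    for (grp in split(dt, by = c("chrom", "strand"), sorted = TRUE)) {
      key <- paste0(grp$chrom[1], "\r", grp$strand[1])
      # positions stored as double once so binary searches never re-coerce
      assign(key, list(pos = as.double(grp$pos), count = grp$count,
                       cum = cumsum(grp$count)), envir = idx)
    }
  }
  structure(list(data = dt, index = idx, chrom_sizes = chrom_sizes),
            class = "signal_track")
}

#' @export
print.signal_track <- function(x, ...) {
  cat("signal_track:", nrow(x$data), "positions,",
      sum(x$data$count), "reads on",
      length(unique(x$data$chrom)), "chromosome(s)\n")
  invisible(x)
}

#' Total reads in a track
#' @param track a `signal_track`.
#' @return Numeric total count.
#' @export
track_total <- function(track) sum(track$data$count)

# rightmost index i with pos[i] <= x, vectorized over x; pos sorted.
# (findInterval re-validates sortedness on every call, which is O(n) and
# dominates per-gene window queries on megabase tracks)
.bsearch_le <- function(pos, x) {
  lo <- integer(length(x))
  hi <- rep.int(length(pos), length(x))
  while (TRUE) {
    open <- lo < hi
    if (!any(open)) break
    mid <- (lo + hi + 1L) %/% 2L
    le <- open & pos[pmax(mid, 1L)] <= x
    lo[le] <- mid[le]
    hi[open & !le] <- mid[open & !le] - 1L
  }
  lo
}

#' Sum counts over genomic windows
#'
#' Vectorised range-sum over `[from, to)` windows on one chromosome/strand.
#'
#' @param track a `signal_track`.
#' @param chrom chromosome name (scalar).
#' @param strand "+" or "-" (scalar).
#' @param from,to integer vectors of 0-based half-open bounds.
#' @return Numeric vector of window sums.
#' @export
track_window_sums <- function(track, chrom, strand, from, to) {
  key <- paste0(chrom, "\r", strand)
  ix <- if (exists(key, envir = track$index, inherits = FALSE)) {
    get(key, envir = track$index)
  } else NULL
  if (is.null(ix)) return(numeric(length(from)))
  lo <- .bsearch_le(ix$pos, from - 0.5)
  hi <- .bsearch_le(ix$pos, to - 0.5)
  cum0 <- c(0, ix$cum)
  cum0[hi + 1L] - cum0[lo + 1L]
}

#' Extract stored positions within a window
#'
#' @inheritParams track_window_sums
#' @return data.frame with columns `pos`, `count` (0-based positions).
#' @export
track_positions <- function(track, chrom, strand, from, to) {
  key <- paste0(chrom, "\r", strand)
  ix <- if (exists(key, envir = track$index, inherits = FALSE)) {
    get(key, envir = track$index)
  } else NULL
  if (is.null(ix)) return(data.frame(pos = integer(), count = numeric()))
  lo <- .bsearch_le(ix$pos, from - 0.5)
  hi <- .bsearch_le(ix$pos, to - 0.5)
  if (hi <= lo) return(data.frame(pos = integer(), count = numeric()))
  sel <- (lo + 1L):hi
  data.frame(pos = as.integer(ix$pos[sel]), count = ix$count[sel])
}

#' Pool several tracks into one
#'
#' Used to combine replicate libraries of one condition before window-level
#' summaries (antisense fractions, pause-window detection).
#'
#' @param tracks list of `signal_track` objects.
#' @return A pooled `signal_track`.
#' @export
pool_tracks <- function(tracks) {
  stopifnot(length(tracks) >= 1)
  dt <- data.table::rbindlist(lapply(tracks, function(t) t$data))
  signal_track(dt$chrom, dt$strand, dt$pos, dt$count,
               chrom_sizes = tracks[[1]]$chrom_sizes)
}
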