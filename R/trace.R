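#' Two-channel binned fluorescence trace
#'
#' The raw-data container of the package: donor and acceptor photon counts in
#' aligned time bins, plus an optional direct-excitation acceptor channel for
#' alternating-excitation data.
#'
#' @param donor,acceptor Non-negative integer photon counts per bin, equal
#'   length.
#' @param bin_width Bin width in seconds (> 0).  smFRET burst analysis
#'   conventionally uses 1 ms bins; subpopulation-selective FCS correlates the
#'   raw acquisition binning (0.96 us here).
#' @param direct_acceptor Optional third channel of the same length.
#' @param origin_time Start time of the first bin, seconds.
#' @return An object of class `binned_trace`.
#' @examples
#' tr <- binned_trace(donor = c(1, 2, 3, 4), acceptor = c(0, 1, 0, 2),
#'                    bin_width = 1e-3)
#' rebin(tr, 2)
#' @export
binned_trace <- function(donor, acceptor, bin_width,
                         direct_acceptor = NULL, origin_time = 0) {
  if (!is.numeric(bin_width) || length(bin_width) != 1L || bin_width <= 0) {
    stop("`bin_width` must be a single positive number (seconds)")
  }
  if (length(donor) != length(acceptor)) {
    stop("`donor` and `acceptor` must have the same length")
  }
  check_counts <- function(x, nm) {
    if (anyNA(x) || any(x < 0) || any(x != floor(x))) {
      stop(sprintf("`%s` must contain non-negative integer counts", nm))
    }
  }
  check_counts(donor, "donor")
  check_counts(acceptor, "acceptor")
  if (!is.null(direct_acceptor)) {
    if (length(direct_acceptor) != length(donor)) {
      stop("`direct_acceptor` must match the channel length")
    }
    check_counts(direct_acceptor, "direct_acceptor")
    direct_acceptor <- as.integer(direct_acceptor)
  }
  structure(list(bin_width = as.numeric(bin_width),
                 donor = as.integer(donor),
                 acceptor = as.integer(acceptor),
                 direct_acceptor = direct_acceptor,
                 origin_time = as.numeric(origin_time)),
            class = "binned_trace")
}

#' @export
length.binned_trace <- function(x) length(x$donor)

#' @export
print.binned_trace <- function(x, ...) {
  cat(sprintf("<binned_trace> %d bins x %.3g s (%.3g s total)\n",
              length(x), x$bin_width, length(x) * x$bin_width))
  cat(sprintf("  donor: %d counts, acceptor: %d counts%s\n",
              sum(x$donor), sum(x$acceptor),
              if (is.null(x$direct_acceptor)) "" else ", direct acceptor present"))
  invisible(x)
}

#' Rebin a trace by summing consecutive bins
#'
#' Bridges the acquisition binning (sub-microsecond) and the burst-analysis
#' binning (milliseconds).  A trailing remainder shorter than `factor` is
#' dropped.
#'
#' @param trace A [binned_trace()].
#' @param factor Positive integer number of input bins per output bin.
#' @return A `binned_trace` with bin width `factor` times the input's.
#' @export
rebin <- function(trace, factor) {
  stopifnot(inherits(trace, "binned_trace"))
  if (!is.numeric(factor) || length(factor) != 1L || factor < 1 ||
      factor != floor(factor)) {
    stop("`factor` must be a positive integer")
  }
  factor <- as.integer(factor)
  if (length(trace) < factor) stop("trace shorter than `factor`")
  binned_trace(
    donor = cpp_rebin_sum(trace$donor, factor),
    acceptor = cpp_rebin_sum(trace$acceptor, factor),
    bin_width = trace$bin_width * factor,
    direct_acceptor = if (!is.null(trace$direct_acceptor)) {
      cpp_rebin_sum(trace$direct_acceptor, factor)
    },
    origin_time = trace$origin_time
  )
}

#' Detect fluorescence bursts by peak threshold
#'
#' A burst is a maximal run of consecutive bins whose summed donor + acceptor
#' count is at or above the peak threshold.  Bins outside all bursts are the
#' background bins.
#'
#' @param trace A [binned_trace()], normally at the burst-analysis binning.
#' @param peak_threshold Counts per bin (>= 0) separating signal from
#'   background.
#' @param background Optional [background_model()]; when given, the apparent
#'   FRET efficiency of each burst is background-corrected (rate x burst
#'   length subtracted per channel before forming the ratio).
#' @return A data frame of class `burst_table` with columns `start_bin`
#'   (1-based, inclusive), `end_bin` (inclusive), `donor_sum`, `acceptor_sum`,
#'   `e_app`, ordered by `start_bin`.
#' @export
detect_bursts <- function(trace, peak_threshold, background = NULL) {
  stopifnot(inherits(trace, "binned_trace"))
  if (!is.numeric(peak_threshold) || length(peak_threshold) != 1L ||
      peak_threshold < 0) {
    stop("`peak_threshold` must be a single non-negative number")
  }
  total <- trace$donor + trace$acceptor
  above <- total >= peak_threshold
  out <- if (length(above) == 0L || !any(above)) {
    data.frame(start_bin = integer(), end_bin = integer(),
               donor_sum = integer(), acceptor_sum = integer(),
               e_app = numeric())
  } else {
    r <- rle(above)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- r$values
    starts <- starts[keep]
    ends <- ends[keep]
    cd <- c(0L, cumsum(trace$donor))
    ca <- c(0L, cumsum(trace$acceptor))
    d <- cd[ends + 1L] - cd[starts]
    a <- ca[ends + 1L] - ca[starts]
    data.frame(start_bin = starts, end_bin = ends,
               donor_sum = d, acceptor_sum = a,
               e_app = burst_e_app(d, a, ends - starts + 1L, background))
  }
  structure(out, class = c("burst_table", "data.frame"),
            bin_width = trace$bin_width, threshold = peak_threshold,
            n_bins = length(trace))
}

# Apparent FRET efficiency of bursts, optionally background-corrected,
# clamped to [-1, 1].
burst_e_app <- function(donor_sum, acceptor_sum, n_bins, background = NULL) {
  if (is.null(background)) {
    d <- donor_sum
    a <- acceptor_sum
  } else {
    d <- donor_sum - background$donor_rate * n_bins
    a <- acceptor_sum - background$acceptor_rate * n_bins
  }
  e <- ifelse(d + a == 0, NA_real_, a / (d + a))
  pmin(1, pmax(-1, e))
}

#' Recompute burst FRET efficiencies with background correction
#'
#' @param bursts A `burst_table` from [detect_bursts()].
#' @param background A [background_model()].
#' @return The burst table with `e_app` replaced by the corrected value.
#' @export
background_correct_bursts <- function(bursts, background) {
  stopifnot(inherits(bursts, "burst_table"))
  bursts$e_app <- burst_e_app(bursts$donor_sum, bursts$acceptor_sum,
                              bursts$end_bin - bursts$start_bin + 1L,
                              background)
  bursts
}

#' Per-channel Poisson background model
#'
#' @param donor_rate,acceptor_rate Mean background counts per bin (>= 0).
#' @return An object of class `background_model`.
#' @export
background_model <- function(donor_rate, acceptor_rate) {
  if (donor_rate < 0 || acceptor_rate < 0) stop("background rates must be >= 0")
  structure(list(donor_rate = as.numeric(donor_rate),
                 acceptor_rate = as.numeric(acceptor_rate)),
            class = "background_model")
}

#' Estimate the background rates from non-burst bins
#'
#' The per-channel rate is the mean count over all bins not covered by any
#' burst.
#'
#' @param trace The [binned_trace()] the bursts were detected on.
#' @param bursts The `burst_table` from [detect_bursts()] on that trace.
#' @return A [background_model()].
#' @export
estimate_background <- function(trace, bursts) {
  stopifnot(inherits(trace, "binned_trace"))
  mask <- rep(TRUE, length(trace))
  if (nrow(bursts) > 0L) {
    for (i in seq_len(nrow(bursts))) {
      mask[bursts$start_bin[i]:bursts$end_bin[i]] <- FALSE
    }
  }
  if (!any(mask)) stop("no background bins: bursts cover the whole trace")
  background_model(mean(trace$donor[mask]), mean(trace$acceptor[mask]))
}

#' Replace unselected trace segments by Poisson background
#'
#' Bins inside the kept windows are copied verbatim; every other bin is
#' redrawn per channel from a Poisson law at the background rates.  This is
#' the masking step of subpopulation-selective FCS: the correlation of the
#' masked trace carries the diffusion information of the kept bursts only,
#' over a stationary background.
#'
#' @param trace A [binned_trace()] (normally the fine acquisition binning).
#' @param keep Windows to keep: a `burst_table` or a data frame with
#'   `start_bin`/`end_bin` columns (1-based, inclusive) referring to `trace`'s
#'   binning.  Must be non-overlapping.
#' @param background A [background_model()] at `trace`'s binning.
#' @param seed Integer seed fixing the replacement noise stream.
#' @return A `binned_trace` of the same length and bin width.
#' @export
poisson_masked_trace <- function(trace, keep, background, seed) {
  stopifnot(inherits(trace, "binned_trace"),
            inherits(background, "background_model"))
  n <- length(trace)
  if (nrow(keep) > 0L) {
    o <- order(keep$start_bin)
    keep <- keep[o, , drop = FALSE]
    if (any(keep$start_bin < 1) || any(keep$end_bin > n) ||
        any(keep$end_bin < keep$start_bin)) {
      stop("keep windows must lie within the trace")
    }
    if (nrow(keep) > 1L &&
        any(keep$start_bin[-1L] <= keep$end_bin[-nrow(keep)])) {
      stop("keep windows must not overlap")
    }
  }
  ws <- as.numeric(keep$start_bin)
  we <- as.numeric(keep$end_bin)
  with_seed(seed, {
    donor <- cpp_mask_poisson(trace$donor, ws, we, background$donor_rate)
    acceptor <- cpp_mask_poisson(trace$acceptor, ws, we,
                                 background$acceptor_rate)
    binned_trace(donor, acceptor, trace$bin_width,
                 origin_time = trace$origin_time)
  })
}

#' Map burst windows between binnings by time interval
#'
#' Converts bursts found on a coarse (burst-analysis) binning into bin windows
#' on the fine (acquisition) binning of the same recording, covering the same
#' time intervals.  Adjacent windows that touch after conversion are merged so
#' the result is valid input for [poisson_masked_trace()].
#'
#' @param bursts A `burst_table` detected on the coarse trace.
#' @param coarse_bin_width,fine_bin_width Bin widths in seconds.
#' @param n_fine Number of bins of the fine trace (windows are clamped to it).
#' @return A data frame with `start_bin`, `end_bin` (1-based, inclusive) on
#'   the fine binning.
#' @export
map_windows <- function(bursts, coarse_bin_width, fine_bin_width, n_fine) {
  if (nrow(bursts) == 0L) {
    return(data.frame(start_bin = numeric(), end_bin = numeric()))
  }
  t0 <- (bursts$start_bin - 1) * coarse_bin_width
  t1 <- bursts$end_bin * coarse_bin_width
  start <- pmax(1, floor(t0 / fine_bin_width) + 1)
  end <- pmin(n_fine, ceiling(t1 / fine_bin_width))
  o <- order(start)
  start <- start[o]
  end <- end[o]
  # merge touching/overlapping windows
  ms <- start[1]
  me <- end[1]
  out_s <- numeric(0)
  out_e <- numeric(0)
  if (length(start) > 1L) {
    for (i in 2:length(start)) {
      if (start[i] <= me + 1) {
        me <- max(me, end[i])
      } else {
        out_s <- c(out_s, ms)
        out_e <- c(out_e, me)
        ms <- start[i]
        me <- end[i]
      }
    }
  }
  data.frame(start_bin = c(out_s, ms), end_bin = c(out_e, me))
}

#' Read / write a binned trace as delimited text
#'
#' The on-disk format is tab-separated text with comment header lines
#' `# bin_width_s <w>` and `# origin_time_s <t>` followed by columns
#' `bin_index`, `donor`, `acceptor` and optionally `direct_acceptor`.
#'
#' @param path File path.
#' @param trace A [binned_trace()] (for `write_trace`).
#' @return `read_trace` returns a `binned_trace`; `write_trace` returns
#'   `path` invisibly.
#' @export
read_trace <- function(path) {
  if (!file.exists(path)) stop("trace file not found: ", path)
  hdr <- readLines(path, n = 10L)
  hdr <- hdr[startsWith(hdr, "#")]
  get_attr <- function(key, default = NULL) {
    ln <- grep(paste0("^#\\s*", key), hdr, value = TRUE)
    if (length(ln) == 0L) {
      if (is.null(default)) stop("missing header `", key, "` in ", path)
      return(default)
    }
    as.numeric(sub(paste0("^#\\s*", key, "\\s+"), "", ln[1L]))
  }
  d <- read.table(path, header = TRUE, sep = "\t", comment.char = "#")
  binned_trace(donor = d$donor, acceptor = d$acceptor,
               bin_width = get_attr("bin_width_s"),
               direct_acceptor = d[["direct_acceptor"]],
               origin_time = get_attr("origin_time_s", 0))
}

#' @rdname read_trace
#' @export
write_trace <- function(trace, path) {
  stopifnot(inherits(trace, "binned_trace"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# bin_width_s %.17g", trace$bin_width),
               sprintf("# origin_time_s %.17g", trace$origin_time)), con)
  d <- data.frame(bin_index = seq_along(trace$donor), donor = trace$donor,
                  acceptor = trace$acceptor)
  if (!is.null(trace$direct_acceptor)) d$direct_acceptor <- trace$direct_acceptor
  write.table(d, con, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a burst table as delimited text
#'
#' @param bursts A `burst_table`.
#' @param path File path.
#' @export
write_bursts <- function(bursts, path) {
  write.table(as.data.frame(bursts), path, sep = "\t", row.names = FALSE,
              quote = FALSE)
  invisible(path)
}
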