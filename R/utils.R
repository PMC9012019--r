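#' Round half away from zero
#'
#' Fixed-point rounding with the "round half up" convention, used for all
#' reported percentages so that printed two-decimal figures are exactly
#' reproducible (base [round()] rounds half to even).
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 2) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring the
# caller's stream afterwards.  All stochastic operations in the package route
# their randomness through this helper so no call leaks global RNG state.
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  code
}

# 1-based inclusive <-> 0-based half-open window conversion lives here and
# nowhere else (VCF coordinates are 1-based; BED export is 0-based half-open).
to_bed_coords <- function(start1, end1) {
  data.frame(start = start1 - 1L, end = end1)
}

# Tile windows over [anchor, last]: returns starts (1-based).  step == size
# gives non-overlapping windows.
window_starts <- function(anchor, last, size, step) {
  if (size <= 0 || step <= 0) stop("window size and step must be positive")
  if (last < anchor) return(integer(0))
  seq.int(from = anchor, to = last, by = step)
}

# Sum `values` (aligned with sorted positions `pos`) over each [start, end]
# window via cumulative sums; returns matrix-like list with per-window sums and
# site counts.  Sites flagged FALSE in `usable` contribute nothing and are not
# counted.
window_aggregate <- function(pos, values, usable, starts, size) {
  stopifnot(!is.unsorted(pos))
  v <- ifelse(usable, values, 0)
  cs <- cumsum(c(0, v))
  cn <- cumsum(c(0, as.integer(usable)))
  ends <- starts + size - 1
  i0 <- findInterval(starts - 0.5, pos)      # sites strictly before start
  i1 <- findInterval(ends + 0.5 - 1e-9, pos) # sites <= end
  list(sum = cs[i1 + 1] - cs[i0 + 1], n = cn[i1 + 1] - cn[i0 + 1])
}
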