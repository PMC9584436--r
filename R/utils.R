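#' @importFrom rlang %||% abort warn .data
#' @importFrom tibble tibble as_tibble
#' @importFrom dplyr arrange mutate filter select bind_rows group_by ungroup
#'   summarise left_join row_number desc n
#' @importFrom purrr map map_dbl map_int map2
#' @importFrom stats rnorm runif rbeta sd median setNames
#' @importFrom utils head tail
NULL

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(as.integer(seed %% 2147483647L))
  force(code)
}

# Derive a per-volume / per-stage child seed that stays inside 32-bit range.
child_seed <- function(seed, index, salt = 0L) {
  as.integer((as.numeric(seed) * 1009 + as.numeric(index) * 9973 +
                as.numeric(salt) * 31 + 1) %% 2147483647)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

stopif_not <- function(cond, msg) if (!isTRUE(cond)) abort(msg)

# Pixel coordinates are 0-based; boxes are half-open [x, x+w) x [y, y+h).
# A volume is a numeric array dim c(H, W, Z); value at pixel (x, y, z) is
# vol[y + 1, x + 1, z].
box_center <- function(x, y, w, h) cbind(x + w / 2, y + h / 2)

empty_regions <- function() {
  tibble(x = numeric(), y = numeric(), w = numeric(), h = numeric(),
         z = integer(), score = numeric(), mean_intensity = numeric())
}

# Mean pixel intensity of a box over one frame matrix (H x W), clipped to the
# image; returns NA for a box fully outside.
box_mean_intensity <- function(frame, x, y, w, h) {
  H <- nrow(frame); W <- ncol(frame)
  x0 <- max(0L, floor(x)); y0 <- max(0L, floor(y))
  x1 <- min(W, ceiling(x + w)); y1 <- min(H, ceiling(y + h))
  if (x1 <= x0 || y1 <= y0) return(NA_real_)
  mean(frame[(y0 + 1):y1, (x0 + 1):x1])
}
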