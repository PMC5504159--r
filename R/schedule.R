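#' Joint t1/relaxation-delay sampling schedules
#'
#' A joint schedule is an ordered list of `(t1_index, trelax)` pairs drawn
#' from the full grid formed by the t1 points and the relaxation-delay
#' universe of a geometry.  All pairs are unique; `t1_index` is a 0-based
#' grid index and `trelax` a delay in seconds that must lie on the
#' geometry's mesh.
#'
#' @param t1_index Integer vector of 0-based t1 grid indices.
#' @param trelax Numeric vector of relaxation delays (s).
#' @param geometry The [acquisition_geometry()] the schedule belongs to.
#' @return An object of class `"joint_schedule"`: a data frame with columns
#'   `t1_index` and `trelax`, the geometry attached as an attribute.
#' @export
joint_schedule <- function(t1_index, trelax, geometry) {
  stopifnot(inherits(geometry, "acquisition_geometry"),
            length(t1_index) == length(trelax))
  t1_index <- as.integer(t1_index)
  if (length(t1_index)) {
    bad <- which(t1_index < 0L | t1_index >= geometry$n_t1)
    if (length(bad))
      stop(sprintf("t1 index out of range at row(s) %s",
                   paste(bad, collapse = ", ")))
    uni <- delay_universe(geometry)
    j <- delay_index(trelax, geometry)
    bad <- which(is.na(j))
    if (length(bad))
      stop(sprintf("relaxation delay not in the mesh universe at row(s) %s",
                   paste(bad, collapse = ", ")))
    trelax <- uni[j]  # snap to exact universe values
    key <- paste(t1_index, j)
    if (anyDuplicated(key))
      stop(sprintf("duplicate (t1_index, trelax) pair at row(s) %s",
                   paste(which(duplicated(key)), collapse = ", ")))
  }
  structure(data.frame(t1_index = t1_index, trelax = as.numeric(trelax)),
            geometry = geometry,
            class = c("joint_schedule", "data.frame"))
}

# map delays to 1-based indices in the delay universe (NA when off-mesh)
delay_index <- function(trelax, geometry) {
  uni <- delay_universe(geometry)
  j <- round((trelax - geometry$trelax_min) / geometry$trelax_mesh) + 1
  ok <- j >= 1 & j <= length(uni) &
    abs(trelax - (geometry$trelax_min + (j - 1) * geometry$trelax_mesh)) <
      1e-6 * geometry$trelax_mesh + 1e-12
  j[!ok] <- NA_integer_
  as.integer(j)
}

#' @export
print.joint_schedule <- function(x, ...) {
  geo <- attr(x, "geometry")
  cat(sprintf("Joint NUS schedule: %d of %d grid points (%.2f%%)\n",
              nrow(x), geo$n_t1 * length(delay_universe(geo)),
              100 * nrow(x) / (geo$n_t1 * length(delay_universe(geo)))))
  invisible(x)
}

# Deterministic per-cell sampling priorities over the joint grid.
# Each (t1, delay) cell gets one uniform variate from `seed`; taking the
# n cells of lowest priority is a uniform draw without replacement, and
# the construction is consistent under nesting: the m lowest among the n
# lowest are the m lowest overall.
grid_priorities <- function(geometry, seed) {
  nd <- length(delay_universe(geometry))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed))
  matrix(stats::runif(geometry$n_t1 * nd), nrow = geometry$n_t1)  # [t1+1, j]
}

#' Generate a joint NUS schedule
#'
#' Draws `n_points` unique `(t1, trelax)` pairs uniformly at random without
#' replacement from the full joint grid.  Sampling is implemented by
#' assigning each grid cell a deterministic pseudo-random priority from
#' `seed` and keeping the `n_points` cells of lowest priority, so that the
#' draw is reproducible and consistent under later [subsample_schedule()]
#' calls with the same seed.
#'
#' @param geometry An [acquisition_geometry()].
#' @param n_points Number of schedule points, at most the joint grid size.
#' @param seed Integer seed.
#' @param force_first_point If `TRUE`, the pair `(t1 = 0, smallest delay)`
#'   is forced into the schedule (replacing the highest-priority drawn
#'   cell if necessary).  Off by default.
#' @return A [joint_schedule()], rows in random (priority) order.
#' @export
generate_schedule <- function(geometry, n_points, seed,
                              force_first_point = FALSE) {
  stopifnot(inherits(geometry, "acquisition_geometry"), n_points >= 0)
  uni <- delay_universe(geometry)
  total <- geometry$n_t1 * length(uni)
  if (n_points > total)
    stop(sprintf("requested %d points but the joint grid has only %d",
                 n_points, total))
  pri <- grid_priorities(geometry, seed)
  ord <- order(pri)                      # column-major linear indices
  keep <- ord[seq_len(n_points)]
  if (force_first_point && n_points >= 1 && !(1L %in% keep))
    keep[n_points] <- 1L                 # cell (t1=0, first delay)
  t1 <- (keep - 1L) %% geometry$n_t1
  j <- (keep - 1L) %/% geometry$n_t1 + 1L
  joint_schedule(t1, uni[j], geometry)
}

#' Subsample an existing schedule
#'
#' Keeps a uniformly random subset of `n_points` rows, preserving the
#' parent's row order.  The subset is chosen by per-cell priorities derived
#' from `seed`, so subsampling to `n` and then to `m < n` with the same
#' seed gives exactly the same schedule as one subsample to `m` (nested
#' sampling levels share their points, as when truncating an acquisition).
#'
#' @param schedule A [joint_schedule()].
#' @param n_points Target size, at most `nrow(schedule)`.
#' @param seed Integer seed.
#' @return A [joint_schedule()] whose rows are a subset of the parent's.
#' @export
subsample_schedule <- function(schedule, n_points, seed) {
  stopifnot(inherits(schedule, "joint_schedule"))
  if (n_points > nrow(schedule))
    stop(sprintf("cannot subsample %d points from a %d-point schedule",
                 n_points, nrow(schedule)))
  if (n_points == nrow(schedule)) return(schedule)
  geo <- attr(schedule, "geometry")
  pri <- grid_priorities(geo, seed)
  p <- pri[cbind(schedule$t1_index + 1L, delay_index(schedule$trelax, geo))]
  keep <- sort(order(p)[seq_len(n_points)])   # keep parent order
  joint_schedule(schedule$t1_index[keep], schedule$trelax[keep], geo)
}

#' Write or read a schedule exchange file
#'
#' Plain-text, nuslist-style: two whitespace-separated columns, the 0-based
#' t1 grid index and the relaxation delay in seconds (printed with enough
#' digits to round-trip exactly).  Lines starting with `#` are comments.
#'
#' @param schedule A [joint_schedule()].
#' @param path File path.
#' @param geometry Geometry used to validate delays on read.
#' @return `read_schedule()` returns a [joint_schedule()];
#'   `write_schedule()` returns `path` invisibly.
#' @export
write_schedule <- function(schedule, path) {
  stopifnot(inherits(schedule, "joint_schedule"))
  lines <- sprintf("%d %.17g", schedule$t1_index, schedule$trelax)
  writeLines(c("# joint NUS schedule: t1_index trelax_s", lines), path)
  invisible(path)
}

#' @rdname write_schedule
#' @export
read_schedule <- function(path, geometry) {
  stopifnot(inherits(geometry, "acquisition_geometry"))
  raw <- readLines(path)
  keep <- !grepl("^\\s*(#|$)", raw)
  lines <- raw[keep]
  lineno <- which(keep)
  if (!length(lines)) return(joint_schedule(integer(), numeric(), geometry))
  parts <- strsplit(trimws(lines), "\\s+")
  bad <- which(lengths(parts) != 2)
  if (length(bad))
    stop(sprintf("malformed schedule line %d: '%s'", lineno[bad[1]], lines[bad[1]]))
  t1 <- suppressWarnings(as.integer(vapply(parts, `[[`, "", 1)))
  tr <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 2)))
  bad <- which(is.na(t1) | is.na(tr))
  if (length(bad))
    stop(sprintf("malformed schedule line %d: '%s'", lineno[bad[1]], lines[bad[1]]))
  joint_schedule(t1, tr, geometry)
}
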