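# Internal helpers shared across modules.

#' Evaluate an expression under a fixed RNG seed, restoring RNG state after
#'
#' @param seed integer seed, or NULL for no seeding
#' @param code expression to evaluate
#' @return value of `code`
#' @keywords internal
#' @noRd
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
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
  force(code)
}

stopifnot_positive <- function(..., .allow_zero = FALSE) {
  args <- list(...)
  nms <- names(args)
  for (i in seq_along(args)) {
    x <- args[[i]]
    bad <- if (.allow_zero) any(!is.finite(x) | x < 0) else any(!is.finite(x) | x <= 0)
    if (bad) {
      stop(sprintf("`%s` must be %s and finite", nms[i],
                   if (.allow_zero) "non-negative" else "positive"), call. = FALSE)
    }
  }
  invisible(TRUE)
}

# population standard deviation (n denominator)
sd_pop <- function(x) {
  n <- length(x)
  if (n == 0L) return(NA_real_)
  m <- mean(x)
  sqrt(sum((x - m)^2) / n)
}

assert_stack <- function(stack) {
  if (!is.array(stack$intensities) || length(dim(stack$intensities)) != 3L) {
    stop("stack intensities must be a 3D array [z, y, x]", call. = FALSE)
  }
  stopifnot_positive(voxel_size_z = stack$voxel_size_z,
                     pixel_size_xy = stack$pixel_size_xy)
  invisible(TRUE)
}

#' Construct an image stack
#'
#' A light container for a 3D fluorescence stack: an intensity array indexed
#' `[z, y, x]` together with the physical voxel sizes needed to convert voxel
#' coordinates to micrometres.
#'
#' @param intensities numeric 3D array, dimensions `(z, y, x)`, arbitrary units
#' @param voxel_size_z axial step between slices, micrometres
#' @param pixel_size_xy lateral pixel size, micrometres
#' @return an object of class `image_stack`
#' @export
image_stack <- function(intensities, voxel_size_z = 0.240, pixel_size_xy = 0.103) {
  s <- structure(list(intensities = intensities,
                      voxel_size_z = voxel_size_z,
                      pixel_size_xy = pixel_size_xy),
                 class = "image_stack")
  assert_stack(s)
  s
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$intensities)
  cat(sprintf("image_stack: %d z-slices x %d x %d px (z step %.3f um, px %.3f um)\n",
              d[1], d[2], d[3], x$voxel_size_z, x$pixel_size_xy))
  invisible(x)
}
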