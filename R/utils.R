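#' @importFrom stats runif rnorm sd
#' @importFrom utils write.table head
NULL

## Avogadro constant, mol^-1
.NA_CONST <- 6.02214076e23

## Angstrom^3 -> liters
.A3_TO_L <- 1e-27

# Leveled logging to stderr; threshold set via options(solvkit.verbose=)
.log <- function(level = c("info", "warn", "error"), ...) {
  level <- match.arg(level)
  if (level == "info" && !isTRUE(getOption("solvkit.verbose", FALSE)))
    return(invisible())
  message(sprintf("[%s] %s", toupper(level), paste0(...)))
}

.validateBox <- function(box) {
  if (!is.numeric(box) || length(box) != 3L || any(!is.finite(box)) ||
      any(box <= 0))
    stop("box must be three positive orthorhombic side lengths in Angstrom",
         call. = FALSE)
  as.numeric(box)
}

# distances beyond min(side)/2 break the minimum-image convention
.checkCutoff <- function(cutoff, box, what = "cutoff") {
  if (cutoff > min(box) / 2 + 1e-9)
    stop(sprintf("%s (%g Å) exceeds min(box side)/2 = %g Å: %s",
                 what, cutoff, min(box) / 2,
                 "minimum-image convention invalid"), call. = FALSE)
  invisible(cutoff)
}

.wrapBox <- function(xyz, box) {
  sweep(xyz, 2, box, function(x, b) x - b * floor(x / b))
}

# k uniform random rotations (normalized quaternions) applied to a rigid
# template; returns a (k * nat) x 3 matrix of rotated offsets, molecule-major
.randomRotatedOffsets <- function(template, k) {
  nat <- nrow(template)
  q <- matrix(rnorm(4 * k), k, 4)
  q <- q / sqrt(rowSums(q^2))
  w <- q[, 1]; qx <- q[, 2]; qy <- q[, 3]; qz <- q[, 4]
  out <- matrix(0, k * nat, 3)
  for (a in seq_len(nat)) {
    v <- template[a, ]
    tx <- 2 * (qy * v[3] - qz * v[2])
    ty <- 2 * (qz * v[1] - qx * v[3])
    tz <- 2 * (qx * v[2] - qy * v[1])
    idx <- (seq_len(k) - 1L) * nat + a
    out[idx, 1] <- v[1] + w * tx + qy * tz - qz * ty
    out[idx, 2] <- v[2] + w * ty + qz * tx - qx * tz
    out[idx, 3] <- v[3] + w * tz + qx * ty - qy * tx
  }
  out
}

# deterministic per-frame RNG stream: seed + frame_index
.frameSeed <- function(seed, frame) {
  s <- as.integer(seed) + as.integer(frame)
  if (is.na(s)) stop("seed + frame index overflows 32-bit integer range")
  s
}
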