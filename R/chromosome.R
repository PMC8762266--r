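#' Define a chromosome with a genetic map
#'
#' A chromosome is described by its physical length in base pairs and a
#' monotone piecewise-linear genetic map translating physical coordinates
#' (bp, 0-based) into genetic coordinates (cM). The default map is uniform
#' at `rate_cM_per_Mb`.
#'
#' @param length_bp Chromosome length in base pairs (positive).
#' @param rate_cM_per_Mb Uniform recombination rate used when `map` is
#'   `NULL`. Default 1 cM/Mb.
#' @param map Optional data frame with columns `bp` and `cM` giving map
#'   anchor points. Must start at `(0, 0)`, be non-decreasing in both
#'   columns, and extend to `length_bp`.
#' @return An object of class `chromosome_spec`.
#' @examples
#' chrom <- chromosome_spec(50e6)
#' bp_to_cM(chrom, c(0, 25e6, 50e6))
#' @export
chromosome_spec <- function(length_bp, rate_cM_per_Mb = 1, map = NULL) {
  length_bp <- as.numeric(length_bp)
  if (length(length_bp) != 1L || !is.finite(length_bp) || length_bp <= 0)
    stop("`length_bp` must be a single positive number", call. = FALSE)
  if (is.null(map)) {
    map <- data.frame(bp = c(0, length_bp),
                      cM = c(0, length_bp / 1e6 * rate_cM_per_Mb))
  }
  if (!is.data.frame(map) || !all(c("bp", "cM") %in% names(map)))
    stop("`map` must be a data frame with columns `bp` and `cM`",
         call. = FALSE)
  map <- map[order(map$bp), , drop = FALSE]
  if (map$bp[1L] != 0 || map$cM[1L] != 0)
    stop("genetic map must start at bp = 0, cM = 0", call. = FALSE)
  if (any(diff(map$bp) < 0) || any(diff(map$cM) < 0))
    stop("genetic map must be non-decreasing", call. = FALSE)
  if (max(map$bp) < length_bp)
    stop("genetic map must extend to `length_bp`", call. = FALSE)
  structure(list(length_bp = length_bp, map = map),
            class = "chromosome_spec")
}

#' @export
print.chromosome_spec <- function(x, ...) {
  cat(sprintf("chromosome_spec: %.0f bp, %.2f cM (%d map anchors)\n",
              x$length_bp, chrom_morgans(x) * 100, nrow(x$map)))
  invisible(x)
}

#' Convert physical to genetic coordinates
#'
#' @param chrom A [chromosome_spec()].
#' @param bp Physical positions (0-based base pairs).
#' @return Genetic positions in cM.
#' @export
bp_to_cM <- function(chrom, bp) {
  stopifnot(inherits(chrom, "chromosome_spec"))
  stats::approx(chrom$map$bp, chrom$map$cM, xout = bp, rule = 2,
                ties = "ordered")$y
}

#' Convert genetic to physical coordinates
#'
#' Inverse of [bp_to_cM()]. On map segments of zero recombination the
#' inverse is not unique; the left-most physical position is returned.
#'
#' @param chrom A [chromosome_spec()].
#' @param cM Genetic positions in cM.
#' @return Physical positions (0-based base pairs).
#' @export
cM_to_bp <- function(chrom, cM) {
  stopifnot(inherits(chrom, "chromosome_spec"))
  stats::approx(chrom$map$cM, chrom$map$bp, xout = cM, rule = 2,
                ties = min)$y
}

#' Total genetic length of a chromosome in Morgans
#' @param chrom A [chromosome_spec()].
#' @return Length in Morgans.
#' @export
chrom_morgans <- function(chrom) {
  stopifnot(inherits(chrom, "chromosome_spec"))
  max(chrom$map$cM) / 100
}
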