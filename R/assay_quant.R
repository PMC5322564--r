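# Closed-form auxiliary quantifications: SURVEYOR densitometry indel
# estimation and caliper tumour volume.

#' SURVEYOR indel percentage from band intensities
#'
#' Estimates the indel percentage from the densitometry of a SURVEYOR
#' nuclease digest: `100 * (1 - sqrt(1 - (b + c) / (a + b + c)))`, where
#' `a` is the integrated intensity of the undigested product and `b`, `c`
#' the integrated intensities of the two cleaved products. The square root
#' accounts for heteroduplex formation by random reannealing of edited and
#' unedited strands. The estimate is scale invariant: multiplying all three
#' intensities by a constant leaves it unchanged.
#'
#' @param a Integrated intensity of the undigested product (>= 0).
#' @param b,c Integrated intensities of the two cleaved products (>= 0).
#' @return Indel percentage in `[0, 100]`.
#' @examples
#' surveyor_indel_percent(a = 1, b = 1, c = 1)  # 100 * (1 - sqrt(1/3))
#' surveyor_indel_percent(a = 5, b = 0, c = 0)  # 0: no cleavage
#' @export
surveyor_indel_percent <- function(a, b, c) {
  if (any(c(a, b, c) < 0)) stop("band intensities must be non-negative")
  total <- a + b + c
  if (any(total == 0)) stop("a + b + c must be positive")
  100 * (1 - sqrt(1 - (b + c) / total))
}

#' Cleaved fraction giving a target SURVEYOR indel percentage
#'
#' Inverse of [surveyor_indel_percent()]: the cleaved intensity fraction
#' `(b + c)/(a + b + c)` that yields indel percentage `p`.
#'
#' @param p Indel percentage in `[0, 100)`.
#' @return Cleaved fraction in `[0, 1)`.
#' @export
surveyor_cleaved_fraction <- function(p) {
  if (any(p < 0 | p >= 100)) stop("p must lie in [0, 100)")
  1 - (1 - p / 100)^2
}

#' Xenograft tumour volume from caliper diameters
#'
#' `(d_short^2 * d_long) / 2` for caliper measurements in mm, with
#' `d_short <= d_long`; the standard modified-ellipsoid estimate.
#'
#' @param d_short,d_long Short and long tumour diameters (mm, > 0).
#' @return Volume in mm^3.
#' @examples
#' tumour_volume(2, 2)  # 4
#' tumour_volume(4, 5)  # 40
#' @export
tumour_volume <- function(d_short, d_long) {
  if (any(d_short <= 0 | d_long <= 0)) stop("diameters must be positive")
  if (any(d_short > d_long)) stop("d_short must not exceed d_long")
  (d_short^2 * d_long) / 2
}
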