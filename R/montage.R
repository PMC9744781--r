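#' @useDynLib erpmarkers, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import tibble
#' @importFrom rlang abort .data
NULL

# Row prefixes of the 10/5 nomenclature mapped to position along the
# nasion-inion arc, in percent (nasion = 0). Lateral rows (FT, T, TP, FTT,
# TTP, TPP) are aliases for their coronal row at large lateral indices.
.row_percent <- c(
  Fp = 10, AFp = 15, AF = 20, AFF = 25, F = 30, FFC = 35, FC = 40, FT = 40,
  FCC = 45, FTT = 45, C = 50, T = 50, CCP = 55, TTP = 55, CP = 60, TP = 60,
  CPP = 65, TPP = 65, P = 70, PPO = 75, PO = 80, POO = 85, O = 90, OI = 95,
  I = 100
)

# Parse a 10/5 label into row prefix and lateral token.
# Returns list(prefix, num (0 for z), half (logical)).
.parse_label <- function(label) {
  m <- regmatches(label, regexec("^([A-Za-z]+?)(z|[0-9]+h?)$", label))[[1]]
  if (length(m) == 0) {
    abort(paste0("cannot parse electrode label '", label, "'"))
  }
  prefix <- m[2]
  tok <- m[3]
  if (identical(tok, "z")) {
    list(prefix = prefix, num = 0L, half = FALSE)
  } else {
    half <- grepl("h$", tok)
    list(prefix = prefix, num = as.integer(sub("h$", "", tok)), half = half)
  }
}

# Spherical angles of a label on an idealized head: a = anterior-posterior
# angle from the vertex (degrees, + anterior), b = lateral angle (+ right).
.label_angles <- function(label) {
  p <- .parse_label(label)
  pct <- .row_percent[[p$prefix]]
  if (is.null(pct)) abort(paste0("unknown 10/5 row prefix in '", label, "'"))
  a <- (50 - pct) / 50 * 90
  if (p$num == 0L) {
    b <- 0
  } else {
    b <- 18 * ceiling(p$num / 2) - if (p$half) 9 else 0
    if (p$num %% 2L == 1L) b <- -b
  }
  c(ap = a, lat = b)
}

# Unit-sphere direction, inclination theta from vertex and azimuth phi.
.label_sphere <- function(label) {
  ang <- .label_angles(label) * pi / 180
  x <- sin(ang[["lat"]])
  y <- sin(ang[["ap"]]) * cos(ang[["lat"]])
  z <- cos(ang[["ap"]]) * cos(ang[["lat"]])
  theta <- acos(pmin(1, pmax(-1, z)))
  phi <- if (theta < 1e-12) 0 else atan2(y, x)
  c(theta = theta * 180 / pi, phi = phi * 180 / pi)
}

.montage_asset <- function() {
  system.file("extdata", "montage_105.tsv", package = "erpmarkers",
              mustWork = TRUE)
}

#' Default 126-channel 10/5 montage
#'
#' Builds the frozen 126-channel scalp montage (10/5 nomenclature, averaged-ears
#' reference) used throughout the package, plus two synthetic bipolar ocular
#' channels (`HEOG`, `VEOG`). Scalp positions are idealized spherical-head 10/5
#' angles derived from the labels themselves; `x`/`y` are the
#' azimuthal-equidistant projection onto the unit head disc (vertex `Cz` at the
#' origin, anterior up, left negative `x`).
#'
#' The channel set is read from the versioned asset
#' `inst/extdata/montage_105.tsv` and is guaranteed to contain every electrode
#' referenced by [marker_registry()].
#'
#' @return An object of class `erp_montage`: a list with
#'   \describe{
#'     \item{channels}{tibble with columns `label`, `theta`, `phi` (degrees),
#'       `x`, `y` (unit-disc projection), `hemisphere`.}
#'     \item{eog_channels}{character, the ocular channel labels.}
#'     \item{reference}{reference descriptor ("averaged ears").}
#'   }
#' @examples
#' m <- build_default_montage()
#' nrow(m$channels)  # 126
#' @export
build_default_montage <- function() {
  tab <- utils::read.table(.montage_asset(), header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  ch <- tibble::tibble(
    label = tab$label,
    theta = tab$theta,
    phi = tab$phi
  )
  rad <- ch$theta / 90
  ch$x <- rad * cos(ch$phi * pi / 180)
  ch$y <- rad * sin(ch$phi * pi / 180)
  ch$hemisphere <- vapply(ch$label, .hemisphere_from_label, character(1))
  if (anyDuplicated(ch$label)) abort("montage labels must be unique")
  structure(
    list(channels = ch, eog_channels = c("HEOG", "VEOG"),
         reference = "averaged ears"),
    class = "erp_montage"
  )
}

#' @export
print.erp_montage <- function(x, ...) {
  cat("<erp_montage> ", nrow(x$channels), " scalp channels + ",
      length(x$eog_channels), " EOG (reference: ", x$reference, ")\n", sep = "")
  invisible(x)
}

#' @export
as_tibble.erp_montage <- function(x, ...) x$channels

# Canonical-case lookup: labels are matched case-insensitively so that common
# variants ("Cpz" vs "CPz") resolve to the same electrode.
.match_label <- function(label, montage) {
  all_labels <- c(montage$channels$label, montage$eog_channels)
  idx <- match(toupper(label), toupper(all_labels))
  if (anyNA(idx)) {
    abort(paste0("unknown electrode label(s): ",
                 paste(label[is.na(idx)], collapse = ", ")))
  }
  all_labels[idx]
}

.hemisphere_from_label <- function(label) {
  p <- .parse_label(label)
  if (p$num == 0L) "midline" else if (p$num %% 2L == 1L) "left" else "right"
}

#' Hemisphere of an electrode
#'
#' Classifies a 10/5 label by the standard numbering convention: odd lateral
#' numbers are left-hemisphere, even numbers right, `z`-suffixed labels midline.
#'
#' @param label electrode label(s), matched case-insensitively.
#' @param montage an `erp_montage`; defaults to [build_default_montage()].
#' @return character vector in `{"left", "midline", "right"}`.
#' @examples
#' hemisphere_of("P7")      # "left"
#' hemisphere_of("PPO10h")  # "right"
#' @export
hemisphere_of <- function(label, montage = build_default_montage()) {
  label <- .match_label(label, montage)
  vapply(label, .hemisphere_from_label, character(1), USE.NAMES = FALSE)
}

#' Homologous (mirror-image) electrode
#'
#' Returns the label at the mirror position in the opposite hemisphere; midline
#' electrodes are their own homolog. An involution: `homolog(homolog(x)) == x`.
#'
#' @inheritParams hemisphere_of
#' @return character vector of labels.
#' @examples
#' homolog("P7")  # "P8"
#' homolog("Oz")  # "Oz"
#' @export
homolog <- function(label, montage = build_default_montage()) {
  label <- .match_label(label, montage)
  out <- vapply(label, function(lb) {
    p <- .parse_label(lb)
    if (p$num == 0L) return(lb)
    n <- if (p$num %% 2L == 1L) p$num + 1L else p$num - 1L
    paste0(p$prefix, n, if (p$half) "h" else "")
  }, character(1), USE.NAMES = FALSE)
  # mirrored labels must exist in the montage
  .match_label(out, montage)
}

#' 2-D head-disc coordinates for plotting
#'
#' Azimuthal-equidistant projection of scalp electrode positions onto the unit
#' disc: `Cz` at the origin, anterior up (+y), left hemisphere at negative `x`.
#' EOG channels are excluded (they have no scalp position).
#'
#' @param montage an `erp_montage`.
#' @return A tibble with columns `label`, `x`, `y`.
#' @export
project_2d <- function(montage) {
  montage$channels[, c("label", "x", "y")]
}
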