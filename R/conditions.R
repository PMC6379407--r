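#' @keywords internal
"_PACKAGE"

#' Gaussian blur levels of the experiment, in degrees of visual angle
#'
#' Standard deviations of the isotropic Gaussian spatial filter applied to
#' every display, indexed by blur level 1 (sharpest) to 5 (most blurred).
#' @export
blur_sigmas <- function() c(0.1, 0.2, 0.5, 0.9, 1.9)

#' Enumerate the experimental conditions
#'
#' The design crosses five blur levels with four inducer/cue arrangements:
#' homogeneous black inducers, homogeneous white inducers, mixed inducers with
#' the black-defined (inverted) triangle cued, and mixed inducers with the
#' white-defined (upright) triangle cued. Black inducers imply an inverted
#' triangle, so the matching triangle cueing black points downward; the
#' white-cued matching triangle points upward. For homogeneous displays the
#' cued polarity is the (only) inducer polarity.
#'
#' @return A data frame with one row per condition and columns
#'   `condition_id`, `inducer_condition` (`"homog_black"`, `"homog_white"`,
#'   `"mixed"`), `cued_polarity` (`"black"`/`"white"`), `cue_orientation`
#'   (`"down"`/`"up"`), `blur_level` (1..5) and `blur_sigma_deg`.
#' @examples
#' nrow(condition_grid())  # 20
#' @export
condition_grid <- function() {
  if (!is.null(.cache$grid)) return(.cache$grid)
  arrangements <- data.frame(
    inducer_condition = c("homog_black", "homog_white", "mixed", "mixed"),
    cued_polarity     = c("black", "white", "black", "white"),
    stringsAsFactors  = FALSE
  )
  g <- merge(arrangements, data.frame(blur_level = 1:5), by = NULL)
  g$blur_sigma_deg <- blur_sigmas()[g$blur_level]
  g$cue_orientation <- ifelse(g$cued_polarity == "black", "down", "up")
  g$condition_id <- condition_id(g$inducer_condition, g$cued_polarity, g$blur_level)
  g <- g[order(g$inducer_condition, g$cued_polarity, g$blur_level),
         c("condition_id", "inducer_condition", "cued_polarity",
           "cue_orientation", "blur_level", "blur_sigma_deg")]
  rownames(g) <- NULL
  opp <- ifelse(g$inducer_condition == "mixed",
                condition_id(g$inducer_condition,
                             ifelse(g$cued_polarity == "black", "white", "black"),
                             g$blur_level),
                g$condition_id)
  .cache$grid <- g
  .cache$opposite <- stats::setNames(opp, g$condition_id)
  g
}

# condition grid and opposite-cue lookup are fixed by the design; cache them
.cache <- new.env(parent = emptyenv())

#' Canonical condition identifier
#'
#' @param inducer_condition one of `"homog_black"`, `"homog_white"`, `"mixed"`
#' @param cued_polarity `"black"` or `"white"`
#' @param blur_level integer 1..5
#' @return character id such as `"mixed.black.b3"`
#' @export
condition_id <- function(inducer_condition, cued_polarity, blur_level) {
  paste0(inducer_condition, ".", cued_polarity, ".b", blur_level)
}

#' Id of the competing cue condition on a mixed display
#'
#' On a mixed display the non-attended illusory triangle is the one defined by
#' the opposite inducer polarity; an attentional lapse selects that surface.
#' Homogeneous displays have no competing surface and map to themselves.
#'
#' @param id a `condition_id` string
#' @return the condition id with the cued polarity swapped (mixed only)
#' @export
opposite_condition_id <- function(id) {
  if (is.null(.cache$opposite)) condition_grid()
  out <- .cache$opposite[id]
  if (anyNA(out)) stop("unknown condition id: ", paste(id[is.na(out)], collapse = ", "))
  unname(out)
}
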