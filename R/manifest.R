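#' Multiphoton imaging design
#'
#' Describes a fully crossed imaging campaign: volumetric stacks of
#' `images_per_stack` optical sections acquired in `n_channels` channels
#' (SHG and TPF), with `stacks_per_gel` stacks per gel, `gels_per_group`
#' gels per experimental group, `n_groups` treatment groups and
#' `n_concentrations` collagen concentrations.
#'
#' @param n_channels,images_per_stack,stacks_per_gel,gels_per_group,n_groups,n_concentrations
#'   Positive integer counts. Defaults reproduce a 2-channel, 11-slice,
#'   3-stack, 4-gel, 2-group, 4-concentration campaign (2112 images).
#' @return An object of class `imaging_design`.
#' @examples
#' manifest_count(imaging_design())  # 2112
#' @export
imaging_design <- function(n_channels = 2, images_per_stack = 11,
                           stacks_per_gel = 3, gels_per_group = 4,
                           n_groups = 2, n_concentrations = 4) {
  vals <- c(
    n_channels = n_channels, images_per_stack = images_per_stack,
    stacks_per_gel = stacks_per_gel, gels_per_group = gels_per_group,
    n_groups = n_groups, n_concentrations = n_concentrations
  )
  if (any(vals < 1) || any(vals != round(vals))) {
    stop_invalid("all design counts must be integers >= 1")
  }
  structure(as.list(setNames(as.integer(vals), names(vals))),
            class = "imaging_design")
}

#' Number of images implied by an imaging design
#'
#' The product of all six design counts.
#'
#' @param design An [imaging_design()].
#' @return A single integer count.
#' @export
manifest_count <- function(design) {
  stopifnot(inherits(design, "imaging_design"))
  as.integer(prod(unlist(design)))
}

#' Enumerated acquisition manifest
#'
#' Expands an [imaging_design()] into one row per image, with identifying
#' coordinates for group, concentration, gel, stack, slice and channel.
#' Its row count always equals [manifest_count()].
#'
#' @inheritParams manifest_count
#' @return A tibble with columns `group`, `concentration`, `gel`, `stack`,
#'   `slice`, `channel`.
#' @export
imaging_manifest <- function(design) {
  stopifnot(inherits(design, "imaging_design"))
  tidyr::expand_grid(
    group = seq_len(design$n_groups),
    concentration = seq_len(design$n_concentrations),
    gel = seq_len(design$gels_per_group),
    stack = seq_len(design$stacks_per_gel),
    slice = seq_len(design$images_per_stack),
    channel = seq_len(design$n_channels)
  )
}
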