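#' Absolute copy number from flow-cytometry mean fluorescence intensities
#'
#' Ratio of the background-corrected, dye-specific sample signal to the
#' background-corrected reference signal, scaled by the known copy number
#' of the reference standard:
#' \deqn{n = \frac{(MFI_{sample,+} - MFI_{sample,-}) - (MFI_{bg,+} - MFI_{bg,-})}
#'                {(MFI_{ref,+} - MFI_{ref,-}) - (MFI_{bg,+} - MFI_{bg,-})}
#'           \times n_{ref}}
#' where +/- denote labelled and unlabelled measurements of the same cells
#' and the background comes from unedited parental cells.
#'
#' @param mfi List or data frame row with fields `sample_plus`,
#'   `sample_minus`, `background_plus`, `background_minus`,
#'   `reference_plus`, `reference_minus` (all >= 0) and `n_reference`
#'   (> 0, copies per cell; the reference standard is typically a line with
#'   ~0.1 million tagged copies per cell).
#' @return Copies per cell. A negative background-corrected sample signal
#'   is clamped to 0 with a warning (dim samples near background).
#' @export
copy_number_from_mfi <- function(mfi) {
  need <- c("sample_plus", "sample_minus", "background_plus",
            "background_minus", "reference_plus", "reference_minus",
            "n_reference")
  miss <- setdiff(need, names(mfi))
  if (length(miss))
    abort_param(paste("missing MFI fields:", paste(miss, collapse = ", ")))
  for (f in setdiff(need, "n_reference")) check_nonneg(mfi[[f]], f)
  check_pos(mfi$n_reference, "n_reference")
  bg <- mfi$background_plus - mfi$background_minus
  sig_sample <- (mfi$sample_plus - mfi$sample_minus) - bg
  sig_ref <- (mfi$reference_plus - mfi$reference_minus) - bg
  if (sig_ref <= 0)
    abort_param("background-corrected reference signal is not positive; reference standard unusable")
  if (sig_sample < 0) {
    warning("background-corrected sample signal is negative; clamping copy number to 0")
    sig_sample <- 0
  }
  sig_sample / sig_ref * mfi$n_reference
}

#' Correct a tagged-protein copy number for tag loss
#'
#' Some of the protein pool has lost its fluorescent tag and is invisible
#' to the dye; western-blot band intensities of the untagged and tagged
#' species rescale the fluorescence-derived copy number to the total:
#' `n_total = (I_untagged + I_tagged) / I_tagged * n_tagged`.
#'
#' @param n_halo Copy number of the tagged species (copies/cell).
#' @param bands List with `intensity_untagged` and `intensity_tagged`
#'   (densitometry units, >= 0; tagged must be > 0).
#' @return Total copies per cell (always >= `n_halo`).
#' @export
correct_for_tag_loss <- function(n_halo, bands) {
  check_nonneg(n_halo, "n_halo")
  check_nonneg(bands$intensity_untagged, "intensity_untagged")
  if (is.null(bands$intensity_tagged) || bands$intensity_tagged <= 0)
    abort_param("`intensity_tagged` must be > 0 for the tag-loss correction")
  (bands$intensity_untagged + bands$intensity_tagged) /
    bands$intensity_tagged * n_halo
}

#' Bound molecules per target site
#'
#' Worked abundance arithmetic: of `n_total` copies, a fraction `f_bound`
#' is chromatin-bound and a fraction `f_target_share` of those is bound at
#' the target class (e.g. telomeres), giving
#' `bound_at_target = n_total * f_bound * f_target_share` molecules spread
#' over `n_targets` sites.
#'
#' @param n_total Total copies per cell.
#' @param f_bound Bound fraction in `[0, 1]`.
#' @param f_target_share Share of bound molecules at the target class.
#' @param n_targets Number of target sites (> 0).
#' @return List with `bound_at_target` and `per_target`.
#' @export
bound_molecules_per_target <- function(n_total, f_bound, f_target_share,
                                       n_targets) {
  check_nonneg(n_total, "n_total")
  check_prob(f_bound, "f_bound"); check_prob(f_target_share, "f_target_share")
  if (is.null(n_targets) || n_targets <= 0)
    abort_param("`n_targets` must be > 0")
  bound <- n_total * f_bound * f_target_share
  list(bound_at_target = bound, per_target = bound / n_targets)
}

#' Read an MFI table and compute copy numbers per row
#'
#' @param path CSV with columns `condition`, `sample_plus`, `sample_minus`,
#'   `background_plus`, `background_minus`, `reference_plus`,
#'   `reference_minus`, `n_reference`.
#' @return Tibble with `condition` and `copies_per_cell`.
#' @export
copy_number_report <- function(path) {
  df <- utils::read.csv(path)
  out <- vapply(seq_len(nrow(df)), function(i)
    copy_number_from_mfi(as.list(df[i, ])), numeric(1))
  tibble::tibble(condition = df$condition, copies_per_cell = out)
}
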