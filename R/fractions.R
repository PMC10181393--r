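#' Directional fiber-volume and porosity fractions
#'
#' Container for one preform's fraction set, all in percent of unit-cell (or
#' structure) volume: directional fiber fractions `V_fw`, `V_ff`, `V_fz`
#' (warp, filling, z), their total `V_fp`, the total porosity
#' `V_tpr = 100 - V_fp`, and the equal-split directional porosities
#' `V_wpr = V_fpr = V_zpr = V_tpr / 3` (see [directional_porosity_split()]).
#'
#' A fraction set is flagged `non_physical` (with a warning) when the total
#' fiber fraction exceeds 100%; values are never clamped.
#'
#' @param V_fw,V_ff,V_fz Directional fiber volume fractions in percent.
#' @param V_fp Total fiber volume fraction in percent. Defaults to the sum
#'   of the three directional fractions (the model-side invariant).
#'   Measured fraction sets may supply an independently determined total
#'   (from bulk density) that need not equal the directional sum; such sets
#'   are marked with the attribute `additive = FALSE`.
#' @param source Optional label for the origin of the numbers, e.g.
#'   `"measured"`, `"analytical"`, `"voxel"`.
#' @param arch Optional architecture code carried for reporting.
#' @return Object of class `fraction_set`: a named list with fields `V_fw`,
#'   `V_ff`, `V_fz`, `V_fp`, `V_wpr`, `V_fpr`, `V_zpr`, `V_tpr` and the
#'   attributes `non_physical`, `additive`, `source`, `arch`.
#' @examples
#' fraction_set(20.06, 7.03, 9.55, source = "measured", arch = "3DW-O-ZO")
#' @export
fraction_set <- function(V_fw, V_ff, V_fz, V_fp = NULL,
                         source = NULL, arch = NULL) {
  stopifnot(is.numeric(V_fw), is.numeric(V_ff), is.numeric(V_fz))
  if (any(c(V_fw, V_ff, V_fz) < 0)) {
    stop("directional fiber fractions must be >= 0")
  }
  additive <- is.null(V_fp)
  if (additive) {
    V_fp <- V_fw + V_ff + V_fz
  } else {
    stopifnot(is.numeric(V_fp), V_fp >= 0)
    additive <- isTRUE(all.equal(V_fp, V_fw + V_ff + V_fz, tolerance = 1e-9))
  }
  non_physical <- V_fp > 100
  if (non_physical) {
    warning(sprintf(
      "total fiber volume fraction %.2f%% exceeds 100%%: geometry is non-physical",
      V_fp
    ))
  }
  V_tpr <- 100 - V_fp
  split <- V_tpr / 3
  structure(
    list(V_fw = V_fw, V_ff = V_ff, V_fz = V_fz, V_fp = V_fp,
         V_wpr = split, V_fpr = split, V_zpr = split, V_tpr = V_tpr),
    non_physical = non_physical, additive = additive,
    source = source, arch = arch,
    class = "fraction_set"
  )
}

#' @export
print.fraction_set <- function(x, digits = 2, ...) {
  src <- attr(x, "source")
  arch <- attr(x, "arch")
  hdr <- paste(c("<fraction_set>", arch, if (!is.null(src)) paste0("(", src, ")")),
               collapse = " ")
  cat(hdr, "\n")
  cat(sprintf("  fiber %%:    warp %.*f  filling %.*f  z %.*f  total %.*f\n",
              digits, x$V_fw, digits, x$V_ff, digits, x$V_fz, digits, x$V_fp))
  cat(sprintf("  porosity %%: per direction %.*f  total %.*f\n",
              digits, x$V_wpr, digits, x$V_tpr))
  if (isTRUE(attr(x, "non_physical"))) cat("  [non-physical: V_fp > 100%]\n")
  invisible(x)
}

#' @export
as.data.frame.fraction_set <- function(x, row.names = NULL, optional = FALSE, ...) {
  data.frame(
    arch = attr(x, "arch") %||% NA_character_,
    source = attr(x, "source") %||% NA_character_,
    V_fw = x$V_fw, V_ff = x$V_ff, V_fz = x$V_fz,
    V_wpr = x$V_wpr, V_fpr = x$V_fpr, V_zpr = x$V_zpr,
    V_fp = x$V_fp, V_tpr = x$V_tpr,
    non_physical = isTRUE(attr(x, "non_physical")),
    stringsAsFactors = FALSE, row.names = row.names
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Total porosity as the complement of the fiber fraction
#'
#' @param V_fp Total fiber volume fraction in percent, in \[0, 100\].
#' @return `100 - V_fp` in percent.
#' @examples
#' porosity_complement(53.52) # 46.48
#' @export
porosity_complement <- function(V_fp) {
  if (!is.numeric(V_fp) || any(!is.finite(V_fp)) ||
      any(V_fp < 0) || any(V_fp > 100)) {
    stop("V_fp must lie in [0, 100]")
  }
  100 - V_fp
}

#' Equal split of total porosity across the three yarn directions
#'
#' Directional porosity is reported as one third of the total porosity per
#' direction. No directional porosity formula accompanies the unit-cell
#' models; the equal split is the rule consistent with reference tables in
#' which the three directional porosity entries are identical and sum to the
#' total.
#'
#' @param V_tpr Total porosity in percent, in \[0, 100\].
#' @return Named numeric vector `c(V_wpr, V_fpr, V_zpr)`, each `V_tpr / 3`.
#' @examples
#' directional_porosity_split(63.34)
#' @export
directional_porosity_split <- function(V_tpr) {
  if (!is.numeric(V_tpr) || !is.finite(V_tpr) || V_tpr < 0 || V_tpr > 100) {
    stop("V_tpr must lie in [0, 100]")
  }
  c(V_wpr = V_tpr / 3, V_fpr = V_tpr / 3, V_zpr = V_tpr / 3)
}
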