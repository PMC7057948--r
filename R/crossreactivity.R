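#' Relative induction of a test compound
#'
#' Expresses the reporter response to a test compound as a percentage of the
#' response to the system's primary effector:
#' `100 * (FL_compound - FL_uninduced) / (FL_primary - FL_uninduced)`.
#' Values may be negative (repression) or exceed 100; they are never
#' clamped. All inputs are OD-normalised absolute fluorescence at the same
#' post-induction time.
#'
#' @param FL_compound Normalised fluorescence with the test compound.
#' @param FL_uninduced Normalised fluorescence without inducer.
#' @param FL_primary Normalised fluorescence with the primary effector.
#' @return Relative induction in percent.
#' @export
relative_induction <- function(FL_compound, FL_uninduced, FL_primary) {
  denom <- FL_primary - FL_uninduced
  if (any(denom == 0)) {
    stop("FL_primary equals FL_uninduced: relative induction undefined")
  }
  100 * (FL_compound - FL_uninduced) / denom
}

#' Build a systems x compounds cross-reactivity matrix
#'
#' From long-format measurements (one row per system/compound pair), builds
#' the relative-induction matrix, the absolute fold-induction matrix
#' (`FL_compound / FL_uninduced`), classifies hits and reports orthogonal
#' systems. The diagonal — each system against its own primary effector —
#' is 100% by construction. Pairs not measured stay `NA` (absent, not
#' zero). Row order of the input does not affect the result.
#'
#' @param measurements data.frame with columns `system`, `compound`,
#'   `FL_compound`, `FL_uninduced`, `FL_primary`.
#' @param primary_map Named character vector: system id -> its primary
#'   compound id. Every system must have a measurement for its primary
#'   compound.
#' @param rel_threshold,fold_threshold Hit thresholds (see
#'   [classify_hits()]).
#' @param orth_threshold Orthogonality threshold (see
#'   [orthogonality_report()]).
#' @return Object of class `crossreactivity_matrix`: list with `systems`,
#'   `compounds`, `rel`, `fold`, `hits` (data.frame), `orthogonal_systems`
#'   and `primary_map`.
#' @export
build_matrix <- function(measurements, primary_map, rel_threshold = 5,
                         fold_threshold = 5, orth_threshold = 5) {
  req <- c("system", "compound", "FL_compound", "FL_uninduced", "FL_primary")
  if (!all(req %in% names(measurements))) {
    stop("missing columns: ", paste(setdiff(req, names(measurements)),
                                    collapse = ", "))
  }
  key <- paste(measurements$system, measurements$compound)
  if (anyDuplicated(key)) {
    stop("duplicated (system, compound) measurement: ",
         key[duplicated(key)][1])
  }
  systems <- sort(unique(measurements$system))
  compounds <- sort(unique(measurements$compound))
  missing_primary <- setdiff(systems, names(primary_map))
  if (length(missing_primary)) {
    stop("no primary effector mapped for system(s): ",
         paste(missing_primary, collapse = ", "))
  }
  for (s in systems) {
    if (!any(measurements$system == s &
             measurements$compound == primary_map[[s]])) {
      stop("system ", s, " lacks a measurement of its primary effector ",
           primary_map[[s]])
    }
  }

  rel <- matrix(NA_real_, length(systems), length(compounds),
                dimnames = list(systems, compounds))
  fold <- rel
  for (i in seq_len(nrow(measurements))) {
    m <- measurements[i, ]
    rel[m$system, m$compound] <- relative_induction(
      m$FL_compound, m$FL_uninduced, m$FL_primary)
    fold[m$system, m$compound] <- fold_induction(m$FL_compound,
                                                 m$FL_uninduced)
  }

  mat <- structure(
    list(systems = systems, compounds = compounds, rel = rel, fold = fold,
         primary_map = primary_map[systems]),
    class = "crossreactivity_matrix"
  )
  mat$hits <- classify_hits(mat, rel_threshold, fold_threshold)
  mat$orthogonal_systems <- orthogonality_report(mat, orth_threshold)
  mat
}

is_primary_cell <- function(mat) {
  outer(mat$systems, mat$compounds, function(s, cpd) {
    unname(mat$primary_map[s]) == cpd
  })
}

#' Classify cross-reactivity hits
#'
#' An off-diagonal (system, non-primary compound) pair is a hit when it
#' passes BOTH rules: relative induction of at least `rel_threshold`
#' percent AND absolute fold induction of at least `fold_threshold`.
#'
#' @param mat `crossreactivity_matrix`.
#' @param rel_threshold Percent threshold (inclusive); default 5.
#' @param fold_threshold Fold threshold (inclusive); default 5.
#' @return data.frame of hits (`system`, `compound`, `rel_pct`, `fold`),
#'   sorted by relative induction descending.
#' @export
classify_hits <- function(mat, rel_threshold = 5, fold_threshold = 5) {
  off <- !is_primary_cell(mat)
  pass <- off & !is.na(mat$rel) & !is.na(mat$fold) &
    mat$rel >= rel_threshold & mat$fold >= fold_threshold
  idx <- which(pass, arr.ind = TRUE)
  res <- data.frame(
    system = mat$systems[idx[, 1]],
    compound = mat$compounds[idx[, 2]],
    rel_pct = mat$rel[pass],
    fold = mat$fold[pass],
    stringsAsFactors = FALSE
  )
  res <- res[order(-res$rel_pct), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Report orthogonal systems
#'
#' A system is orthogonal when every measured off-diagonal relative
#' induction is strictly below `threshold` percent — it responds only to
#' its cognate effector. The boundary is strict ("< 5%"), unlike hit
#' calling which is inclusive ("at least 5%").
#'
#' @param mat `crossreactivity_matrix`.
#' @param threshold Percent threshold (strict); default 5.
#' @return Character vector of orthogonal system ids.
#' @export
orthogonality_report <- function(mat, threshold = 5) {
  off <- !is_primary_cell(mat)
  ok <- vapply(seq_along(mat$systems), function(i) {
    vals <- mat$rel[i, off[i, ]]
    all(is.na(vals) | vals < threshold)
  }, logical(1))
  mat$systems[ok]
}

#' Write a cross-reactivity matrix and hit list
#'
#' @param mat `crossreactivity_matrix`.
#' @param rel_path Output TSV for the relative-induction matrix.
#' @param hits_path Optional output TSV for the hit list.
#' @param orth_path Optional output text file for the orthogonal systems.
#' @export
write_crossreactivity <- function(mat, rel_path, hits_path = NULL,
                                  orth_path = NULL) {
  utils::write.table(data.frame(system = rownames(mat$rel), mat$rel,
                                check.names = FALSE),
                     rel_path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(hits_path)) {
    utils::write.table(mat$hits, hits_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  if (!is.null(orth_path)) {
    writeLines(mat$orthogonal_systems, orth_path)
  }
  invisible(mat)
}

#' @export
print.crossreactivity_matrix <- function(x, ...) {
  cat("crossreactivity_matrix:", length(x$systems), "systems x",
      length(x$compounds), "compounds;", nrow(x$hits), "hit(s);",
      length(x$orthogonal_systems), "orthogonal system(s)\n")
  invisible(x)
}
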