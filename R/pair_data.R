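# Pairwise dataset construction: activity cleaning, pIC50 conversion,
# pair enumeration, similarity filtering, and label balancing.

#' Convert IC50 to pIC50
#'
#' pIC50 = -log10(IC50 in mol/L).
#' @param ic50 numeric IC50 values (> 0)
#' @param unit unit of the input: "M", "mM", "uM" or "nM"
#' @return pIC50 values
#' @export
logConvert <- function(ic50, unit = c("M", "mM", "uM", "nM")) {
  unit <- match.arg(unit)
  if (any(!is.finite(ic50) | ic50 <= 0)) stop("IC50 must be positive")
  fac <- c(M = 1, mM = 1e-3, uM = 1e-6, nM = 1e-9)[[unit]]
  -log10(ic50 * fac)
}

#' Clean a raw activity table into congeneric series
#'
#' Rows with missing activities or qualified values (a '<' or '>' sign in
#' the qualifier column or prefixed to the activity) are discarded, IC50
#' values are converted to pIC50, and series left with fewer than two
#' ligands (unable to form pairs) are dropped.
#'
#' @param raw data.frame with columns \code{ligand_id}, \code{series_id}
#'   and either \code{pic50} or \code{ic50_nM}; optional \code{qualifier},
#'   \code{smiles}, \code{synth_order}
#' @return named list of \linkS4class{CongenericSeries} (no poses attached)
#' @export
cleanActivities <- function(raw) {
  raw <- as.data.frame(raw)
  if (!all(c("ligand_id", "series_id") %in% names(raw))) {
    stop("need ligand_id and series_id columns")
  }
  qual <- as.character(raw$qualifier %||% rep("", nrow(raw)))
  qual[is.na(qual)] <- ""
  if (!is.null(raw$pic50)) {
    act <- raw$pic50
    if (is.character(act)) {
      qual <- ifelse(grepl("^[<>]", trimws(act)), substr(trimws(act), 1, 1), qual)
      act <- suppressWarnings(as.numeric(sub("^[<>]", "", trimws(act))))
    }
    pic50 <- act
  } else if (!is.null(raw$ic50_nM)) {
    act <- raw$ic50_nM
    if (is.character(act)) {
      qual <- ifelse(grepl("^[<>]", trimws(act)), substr(trimws(act), 1, 1), qual)
      act <- suppressWarnings(as.numeric(sub("^[<>]", "", trimws(act))))
    }
    pic50 <- ifelse(is.finite(act) & act > 0, -log10(act * 1e-9), NA_real_)
  } else stop("need a pic50 or ic50_nM column")
  keep <- !(qual %in% c("<", ">")) & is.finite(pic50)
  raw <- raw[keep, , drop = FALSE]
  raw$pic50 <- pic50[keep]
  if (!nrow(raw)) stop("no parseable activity rows")
  out <- list()
  for (sid in unique(raw$series_id)) {
    sub <- raw[raw$series_id == sid, , drop = FALSE]
    if (nrow(sub) < 2L) next  # cannot form ligand pairs
    lig <- data.frame(ligand_id = as.character(sub$ligand_id),
                      pic50 = sub$pic50, stringsAsFactors = FALSE)
    lig$smiles <- as.character(sub$smiles %||% rep(NA_character_, nrow(sub)))
    lig$synth_order <- sub$synth_order %||% seq_len(nrow(sub))
    out[[as.character(sid)]] <- new("CongenericSeries",
                                    seriesId = as.character(sid),
                                    ligands = lig, poses = list())
  }
  if (!length(out)) stop("no series with >= 2 ligands")
  out
}

#' Enumerate ligand pairs of a series
#'
#' All ordered pairs (i, j) with i < j; labels are the pairwise activity
#' difference y(i) - y(j).  With \code{bidirectional = TRUE} each pair is
#' also emitted reversed (label negated), which teaches the antisymmetry
#' of the pairwise task.
#'
#' @param series a \linkS4class{CongenericSeries}
#' @param bidirectional also emit (j, i)
#' @return data.frame: series_id, i, j, label, cls (1 if label > 0, 0 if
#'   < 0, 0.5 on ties — ties are excluded from the classification loss)
#' @export
enumeratePairs <- function(series, bidirectional = FALSE) {
  lg <- series@ligands
  n <- nrow(lg)
  if (n < 2L) stop("need at least two ligands")
  idx <- utils::combn(n, 2L)
  mk <- function(a, b) {
    lab <- lg$pic50[a] - lg$pic50[b]
    data.frame(series_id = series@seriesId,
               i = lg$ligand_id[a], j = lg$ligand_id[b], label = lab,
               cls = ifelse(lab > 0, 1, ifelse(lab < 0, 0, 0.5)),
               stringsAsFactors = FALSE)
  }
  out <- mk(idx[1L, ], idx[2L, ])
  if (bidirectional) out <- rbind(out, mk(idx[2L, ], idx[1L, ]))
  rownames(out) <- NULL
  out
}

#' Filter training pairs by Tanimoto similarity
#'
#' Keeps pairs whose 2-D fingerprint Tanimoto similarity is strictly
#' greater than the threshold.  Intended for training pairs only;
#' evaluation pairs are never filtered.
#'
#' @param pairs data.frame from \code{\link{enumeratePairs}}
#' @param smiles named character vector (names = ligand ids)
#' @param threshold similarity threshold (0.6)
#' @return the filtered pairs with a \code{similarity} column
#' @export
similarityFilter <- function(pairs, smiles, threshold = 0.6) {
  fp <- ligandFingerprints(smiles)
  failed <- attr(fp, "failed")
  if (length(failed)) {
    drop <- pairs$i %in% failed | pairs$j %in% failed
    if (any(drop)) {
      warning(sum(drop), " pairs dropped: unparseable SMILES")
      pairs <- pairs[!drop, , drop = FALSE]
    }
  }
  sim <- vapply(seq_len(nrow(pairs)), function(r) {
    tanimoto(fp, pairs$i[r], pairs$j[r])
  }, 1.0)
  pairs$similarity <- sim
  out <- pairs[sim > threshold, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Balance the pairwise label distribution
#'
#' Histograms the labels in bins of \code{binWidth} pIC50 and resamples so
#' that the occupied-bin count ratio is bounded by \code{capRatio}:
#' high-density bins are undersampled (without replacement) and
#' low-density bins oversampled (with replacement) toward a band around
#' the geometric center of the occupied-bin counts.  Only multiplicities
#' change, never label values; the resampling is seeded.
#'
#' @param pairs data.frame with a \code{label} column
#' @param binWidth histogram bin width in pIC50 units (0.5)
#' @param capRatio maximum occupied-bin max/min count ratio (4)
#' @param seed RNG seed
#' @return resampled pairs data.frame
#' @export
balanceLabels <- function(pairs, binWidth = 0.5, capRatio = 4, seed = 1L) {
  stopifnot(nrow(pairs) >= 1L)
  bin <- floor(pairs$label / binWidth)
  counts <- table(bin)
  if (length(counts) == 1L) {
    warning("single occupied label bin: returned unchanged")
    return(pairs)
  }
  mn <- min(counts); mx <- max(counts)
  center <- sqrt(mn * mx)
  lo <- max(1, ceiling(center / sqrt(capRatio)))
  hi <- max(lo, floor(center * sqrt(capRatio)))
  set.seed(seed)
  take <- integer()
  for (b in names(counts)) {
    rows <- which(bin == as.numeric(b))
    n <- length(rows)
    target <- min(max(n, lo), hi)
    if (target <= n) {
      take <- c(take, rows[sample.int(n, target)])
    } else {
      take <- c(take, rows, rows[sample.int(n, target - n, replace = TRUE)])
    }
  }
  out <- pairs[sort(take), , drop = FALSE]
  rownames(out) <- NULL
  out
}
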