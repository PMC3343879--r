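#' Expand classical alleles into per-position residue dosages
#'
#' Translates each subject's two four-digit calls per locus into additive
#' amino-acid dosages: one column per `(locus, position, residue)` triple,
#' with dosage = number of the subject's two alleles carrying that residue
#' (0/1/2). For a subject with two non-missing, aligned calls the dosages
#' at any position sum to 2 across residues.
#'
#' Residue columns are filtered by the same control-group frequency rule as
#' alleles: only residues with control frequency strictly above
#' `min_control_freq` get a column. Gap (`-`) or undetermined (`?`)
#' residues are treated as missing for that position, not as a residue
#' level; an allele absent from the alignment makes the subject's dosages
#' at that locus missing (a warning reports how many).
#'
#' @param cohort A [cohort_table()] with four-digit calls.
#' @param alignment A `protein_alignment` from [read_alignment()].
#' @param loci Loci to expand (default: cohort loci present in the
#'   alignment).
#' @param min_control_freq Control-frequency threshold for keeping a
#'   residue column (default 0.01).
#' @param dedupe If `TRUE`, columns with identical dosage vectors are
#'   merged (first label kept; merged ids recorded in the `"merged"`
#'   attribute and logged). Useful before stepwise selection where
#'   duplicated columns are pure aliases.
#' @return An object of class `residue_matrix`: list with `dosage`
#'   (numeric matrix, subjects x columns, `NA` where calls are missing),
#'   `columns` (data.frame `locus`, `position`, `residue`, `id`), and
#'   `control_freq` per column. Column ids have the form `"B:97:V"`.
#' @export
expand_residues <- function(cohort, alignment,
                            loci = intersect(cohort$loci, names(alignment)),
                            min_control_freq = 0.01,
                            dedupe = FALSE) {
  sub <- cohort$subjects
  if (!length(loci)) stop_fm("no cohort locus is covered by the alignment")
  is_control <- sub$phenotype == "control"
  dosage_blocks <- list()
  col_blocks <- list()
  freq_blocks <- list()
  n_unknown <- 0L

  for (loc in loci) {
    al <- alignment[[loc]]
    a1 <- sub[[paste0(loc, "_1")]]
    a2 <- sub[[paste0(loc, "_2")]]
    known <- rownames(al$residues)
    unk1 <- !is.na(a1) & !(a1 %in% known)
    unk2 <- !is.na(a2) & !(a2 %in% known)
    n_unknown <- n_unknown + sum(unk1 | unk2)
    # treat unknown alleles as missing calls for this locus
    a1[unk1] <- NA
    a2[unk2] <- NA
    ok <- !is.na(a1) & !is.na(a2)
    # residue lookups: matrix rows = subjects
    r1 <- al$residues[match(a1, known), , drop = FALSE]
    r2 <- al$residues[match(a2, known), , drop = FALSE]
    r1[r1 %in% c("-", "?")] <- NA
    r2[r2 %in% c("-", "?")] <- NA
    for (j in seq_along(al$positions)) {
      pos <- al$positions[j]
      res1 <- r1[, j]
      res2 <- r2[, j]
      ctrl_res <- c(res1[is_control & ok], res2[is_control & ok])
      ctrl_res <- ctrl_res[!is.na(ctrl_res)]
      if (!length(ctrl_res)) next
      ctrl_tab <- table(ctrl_res) / length(ctrl_res)
      # columns are created for residues observed anywhere, filtered on
      # control frequency (residues absent from controls fail > threshold)
      residues <- sort(unique(stats::na.omit(c(res1[ok], res2[ok]))))
      for (res in residues) {
        f <- if (res %in% names(ctrl_tab)) as.numeric(ctrl_tab[[res]]) else 0
        if (f <= min_control_freq) next
        dose <- as.numeric(res1 == res) + as.numeric(res2 == res)
        # one gap-coded allele: count over the non-gap allele only
        one_na <- xor(is.na(res1), is.na(res2))
        dose[one_na] <- as.numeric(
          ifelse(is.na(res1[one_na]), res2[one_na], res1[one_na]) == res
        )
        dose[!ok] <- NA
        id <- paste(loc, pos, res, sep = ":")
        dosage_blocks[[id]] <- dose
        col_blocks[[id]] <- data.frame(locus = loc, position = pos,
                                       residue = res, id = id,
                                       stringsAsFactors = FALSE)
        freq_blocks[[id]] <- f
      }
    }
  }
  if (n_unknown > 0) {
    warning(n_unknown, " subject-locus genotype(s) contained alleles absent ",
            "from the alignment; their residue dosages are set missing",
            call. = FALSE)
  }
  if (!length(dosage_blocks)) stop_fm("no residue column passed the filter")
  dosage <- do.call(cbind, dosage_blocks)
  rownames(dosage) <- sub$id
  columns <- do.call(rbind, col_blocks)
  rownames(columns) <- NULL
  merged <- NULL
  if (dedupe) {
    key <- apply(dosage, 2, paste, collapse = ",")
    dup <- duplicated(key)
    if (any(dup)) {
      merged <- split(colnames(dosage), key)
      merged <- merged[lengths(merged) > 1]
      fm_log("merged ", sum(dup), " residue column(s) identical to an ",
             "earlier column")
      dosage <- dosage[, !dup, drop = FALSE]
      columns <- columns[!dup, , drop = FALSE]
    }
  }
  structure(
    list(dosage = dosage, columns = columns,
         control_freq = unlist(freq_blocks)[colnames(dosage)]),
    merged = merged,
    class = "residue_matrix"
  )
}

#' @export
print.residue_matrix <- function(x, ...) {
  cat("<residue_matrix> ", nrow(x$dosage), " subjects x ", ncol(x$dosage),
      " residue columns over loci ",
      paste(unique(x$columns$locus), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Extract one residue dosage vector
#'
#' Returns the additive dosage for a single `(locus, position, residue)`
#' marker, usable directly as an association term (e.g. Tyr116 coded as
#' `marker_residue(m, "B", 116, "Y")`).
#'
#' @param matrix A `residue_matrix` from [expand_residues()].
#' @param locus,position,residue Marker identity.
#' @return Named numeric vector of per-subject dosages.
#' @export
marker_residue <- function(matrix, locus, position, residue) {
  id <- paste(locus, position, residue, sep = ":")
  j <- match(id, colnames(matrix$dosage))
  if (is.na(j)) {
    here <- matrix$columns[matrix$columns$locus == locus &
                             matrix$columns$position == position, "residue"]
    stop_fm("no column for ", id,
            if (length(here)) {
              paste0("; residues present at ", locus, " position ", position,
                     ": ", paste(here, collapse = ", "))
            } else {
              paste0("; no residues present at ", locus, " position ", position)
            })
  }
  matrix$dosage[, j]
}
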