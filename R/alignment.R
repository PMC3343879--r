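#' Read a positional protein alignment
#'
#' Reads a TSV with one allele per row and one aligned mature-protein
#' position per column; the header row holds the 1-based position indices
#' and is the single source of truth for the numbering convention. The
#' symbol `-` denotes an alignment gap and `?` an undetermined residue;
#' both are treated as missing when residue dosages are formed.
#'
#' The package ships a small synthetic alignment covering the alleles used
#' in its tests and examples (`hla_alignment_synthetic.tsv`); externally
#' supplied full alignments in the same format are accepted.
#'
#' @param path Path to the alignment TSV; default: the packaged fixture.
#' @return An object of class `protein_alignment`: a list with one entry
#'   per locus, each holding `positions` (integer vector) and `residues`
#'   (character matrix, alleles x positions).
#' @export
read_alignment <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "hla_alignment_synthetic.tsv",
                        package = "hlafinemap", mustWork = TRUE)
  }
  if (!file.exists(path)) stop_fm("alignment file not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          colClasses = "character", check.names = FALSE,
                          quote = "", comment.char = "#")
  if (names(df)[1L] != "allele") {
    stop_fm("alignment file must have 'allele' as its first column")
  }
  positions <- suppressWarnings(as.integer(names(df)[-1L]))
  if (anyNA(positions)) {
    stop_fm("alignment header must contain integer position indices")
  }
  parsed <- parse_allele(df$allele)
  out <- list()
  for (loc in unique(parsed$locus)) {
    rows <- which(parsed$locus == loc)
    mat <- as.matrix(df[rows, -1L, drop = FALSE])
    rownames(mat) <- df$allele[rows]
    colnames(mat) <- as.character(positions)
    if (anyDuplicated(rownames(mat))) {
      stop_fm("duplicate allele in alignment: ",
              rownames(mat)[duplicated(rownames(mat))][1L])
    }
    out[[loc]] <- list(positions = positions, residues = mat)
  }
  structure(out, class = "protein_alignment", source = path)
}

#' @export
print.protein_alignment <- function(x, ...) {
  for (loc in names(x)) {
    cat("<protein_alignment> ", loc, ": ", nrow(x[[loc]]$residues),
        " alleles, ", length(x[[loc]]$positions), " positions\n", sep = "")
  }
  invisible(x)
}

# Residue of one allele at one position; NA if allele absent, gap or unknown.
alignment_residue <- function(alignment, allele, position) {
  loc <- allele_locus(allele)
  al <- alignment[[loc]]
  if (is.null(al) || !(allele %in% rownames(al$residues))) return(NA_character_)
  j <- match(position, al$positions)
  if (is.na(j)) return(NA_character_)
  r <- al$residues[allele, j]
  if (r %in% c("-", "?")) NA_character_ else r
}

#' Classify the HLA-B Bw4/Bw6 serological epitope
#'
#' A pure rule on the residue at mature-protein position 80 of HLA-B:
#' isoleucine gives `Bw4_80I`, threonine `Bw4_80T`, asparagine `Bw6`;
#' any other residue, a gap, or an allele absent from the alignment gives
#' `unknown`.
#'
#' @param allele Character vector of HLA-B allele names.
#' @param alignment A `protein_alignment` containing locus B.
#' @return Character vector with values `"Bw4_80I"`, `"Bw4_80T"`, `"Bw6"`
#'   or `"unknown"`.
#' @examples
#' aln <- read_alignment()
#' classify_bw(c("B*57:01", "B*27:05", "B*35:01"), aln)
#' @export
classify_bw <- function(allele, alignment) {
  parsed <- parse_allele(allele)
  if (any(!parsed$missing & parsed$locus != "B")) {
    stop_fm("classify_bw is defined for locus B alleles only")
  }
  vapply(allele, function(a) {
    if (is.na(a)) return("unknown")
    r <- alignment_residue(alignment, a, 80L)
    if (is.na(r)) return("unknown")
    switch(r, I = "Bw4_80I", T = "Bw4_80T", N = "Bw6", "unknown")
  }, character(1), USE.NAMES = FALSE)
}

#' Read named allele-group definitions
#'
#' Groups are a YAML map of group name to allele list (the package ships
#' the B*35 Px/PY split as `allele_groups.yaml`). Overlapping definitions
#' are a configuration error.
#'
#' @param path Path to the YAML file; default: the packaged definition.
#' @return Named list of character vectors.
#' @export
read_allele_groups <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "allele_groups.yaml",
                        package = "hlafinemap", mustWork = TRUE)
  }
  groups <- yaml::read_yaml(path)
  groups <- lapply(groups, as.character)
  all_members <- unlist(groups, use.names = FALSE)
  if (anyDuplicated(all_members)) {
    dup <- all_members[duplicated(all_members)][1L]
    stop_fm("allele '", dup, "' appears in more than one group")
  }
  groups
}

#' Look up the named group of an allele
#'
#' Returns the first group whose member list contains the allele, or `NA`
#' when the allele belongs to none.
#'
#' @param allele Character vector of allele names.
#' @param groups Named list of allele vectors, as from
#'   [read_allele_groups()].
#' @return Character vector of group names (or `NA`).
#' @export
allele_group <- function(allele, groups) {
  all_members <- unlist(groups, use.names = FALSE)
  if (anyDuplicated(all_members)) {
    stop_fm("overlapping group definitions")
  }
  vapply(allele, function(a) {
    if (is.na(a)) return(NA_character_)
    for (g in names(groups)) {
      if (a %in% groups[[g]]) return(g)
    }
    NA_character_
  }, character(1), USE.NAMES = FALSE)
}
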