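#' Read a multiple sequence alignment
#'
#' Reads an aligned FASTA (`.fasta`, `.fa`, `.afa`) or CLUSTAL
#' (`.aln`, `.clustal`) protein alignment. All rows must have equal length;
#' the gap character is `-`.
#'
#' @param path path to the alignment file.
#' @param format `"auto"` (by extension), `"fasta"` or `"clustal"`.
#' @return An object of class `msa`: list with `ids`, `seqs` (named character
#'   vector of aligned rows, upper case) and `n_columns`.
#' @export
read_alignment <- function(path, format = c("auto", "fasta", "clustal")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.(aln|clustal|clu)$", path, ignore.case = TRUE))
      "clustal" else "fasta"
  }
  aln <- tryCatch(
    Biostrings::readAAMultipleAlignment(path, format = format),
    error = function(e) stop("alignment format error in '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  seqs <- toupper(as.character(aln))
  if (length(seqs) < 1) stop("empty alignment: ", path, call. = FALSE)
  if (length(unique(nchar(seqs))) != 1) {
    stop("alignment rows have unequal lengths in '", path, "'", call. = FALSE)
  }
  ids <- names(seqs)
  if (anyDuplicated(ids)) {
    stop("duplicate sequence IDs in alignment: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  structure(list(ids = ids, seqs = seqs, n_columns = nchar(seqs[[1]])),
            class = "msa")
}

#' @export
print.msa <- function(x, ...) {
  cat("MSA:", length(x$ids), "sequences x", x$n_columns, "columns\n")
  invisible(x)
}

#' Map structure residues to alignment columns and reference numbering
#'
#' Maps each residue of a structure to its alignment column through the
#' structure's MSA row, and each column to the author residue numbering of a
#' designated reference row. Residues aligned to reference-gap columns carry a
#' column index but no reference number ("no analogous residue"). The
#' structure's one-letter sequence must match the ungapped MSA row up to a
#' configurable mismatch fraction (engineered point mutants in crystal
#' structures are common).
#'
#' @param alignment an `msa` object.
#' @param seq_id MSA row ID for the structure.
#' @param structure the corresponding `mc_structure` (single chain).
#' @param reference_id MSA row ID of the reference sequence.
#' @param reference_numbers optional integer vector of author residue numbers
#'   for the reference row's ungapped positions (defaults to `1..n`).
#' @param max_mismatch maximum tolerated fraction of mismatched positions
#'   between structure sequence and MSA row (default 0.02).
#' @return An object of class `alignment_map`: list with `structure_id`,
#'   `col_of_res` (named integer; residue key -> 1-based column) and
#'   `ref_of_col` (integer vector over columns; `NA` at reference gaps).
#' @export
build_residue_map <- function(alignment, seq_id, structure, reference_id,
                              reference_numbers = NULL, max_mismatch = 0.02) {
  stopifnot(inherits(alignment, "msa"), inherits(structure, "mc_structure"))
  for (id in c(seq_id, reference_id)) {
    if (!id %in% alignment$ids) {
      stop("sequence '", id, "' not present in alignment", call. = FALSE)
    }
  }
  row <- strsplit(alignment$seqs[[seq_id]], "")[[1]]
  cols <- which(row != "-")
  res_aa <- vapply(structure$residues, function(r) r$aa1 %||% "X", character(1))
  if (length(cols) != length(res_aa)) {
    stop("structure '", structure$structure_id, "' has ", length(res_aa),
         " residues but MSA row '", seq_id, "' has ", length(cols),
         " non-gap positions", call. = FALSE)
  }
  mism <- which(row[cols] != res_aa)
  if (length(mism) > max_mismatch * length(res_aa)) {
    stop("sequence/structure mismatch for '", seq_id, "': first at position ",
         mism[1], " (MSA '", row[cols[mism[1]]], "' vs structure '",
         res_aa[mism[1]], "')", call. = FALSE)
  }
  if (length(mism) > 0) {
    message(length(mism), " mismatched position(s) tolerated for '",
            seq_id, "'")
  }
  col_of_res <- stats::setNames(as.integer(cols), names(structure$residues))

  ref_row <- strsplit(alignment$seqs[[reference_id]], "")[[1]]
  ref_cols <- which(ref_row != "-")
  ref_nums <- reference_numbers %||% seq_along(ref_cols)
  if (length(ref_nums) != length(ref_cols)) {
    stop("reference_numbers length (", length(ref_nums),
         ") does not match ungapped reference length (", length(ref_cols), ")",
         call. = FALSE)
  }
  ref_of_col <- rep(NA_integer_, alignment$n_columns)
  ref_of_col[ref_cols] <- as.integer(ref_nums)

  structure(list(structure_id = structure$structure_id,
                 col_of_res = col_of_res,
                 ref_of_col = ref_of_col),
            class = "alignment_map")
}

#' Per-column sequence conservation
#'
#' Conservation of an alignment column is the frequency of its most common
#' non-gap residue. By default gaps count in the denominator (number of
#' sequences); with `exclude_gaps = TRUE` the denominator is the number of
#' non-gap characters in the column.
#'
#' @param alignment an `msa` object with at least 2 sequences.
#' @param exclude_gaps logical; see above.
#' @return numeric vector of length `n_columns` with values in `[0, 1]`
#'   (all-gap columns give 0).
#' @export
conservation_profile <- function(alignment, exclude_gaps = FALSE) {
  stopifnot(inherits(alignment, "msa"))
  if (length(alignment$ids) < 2) {
    stop("conservation requires >= 2 sequences", call. = FALSE)
  }
  m <- do.call(rbind, strsplit(alignment$seqs, ""))
  apply(m, 2, function(col) {
    res <- col[col != "-"]
    if (length(res) == 0) return(0)
    denom <- if (exclude_gaps) length(res) else length(col)
    max(table(res)) / denom
  })
}
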