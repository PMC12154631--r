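#' Read a multiconformer PDB model
#'
#' Parses a (possibly multiconformer) PDB file into the package's residue-level
#' model. Atoms are grouped per residue into named conformers by their altloc
#' label; atoms with a blank altloc are shared by every conformer of their
#' residue (a residue with only side-chain altlocs still has a complete
#' backbone in each conformer). Hydrogens, waters and non-protein heteroatoms
#' are removed. Selenomethionine (MSE) is kept as a protein residue; other
#' non-standard residues are dropped with a warning.
#'
#' @param path path to a PDB file.
#' @param keep_chains optional character vector of chain IDs to retain.
#' @param structure_id identifier for the structure; defaults to the file name
#'   without extension.
#' @return An object of class `mc_structure`: a list with `structure_id`,
#'   `resolution` (Angstrom, `NA` if absent from the header), `chains`, and
#'   `residues` — a named list (key `chain:resno[icode]`) of residue records.
#'   Each residue record carries `chain`, `resno`, `icode`, `key`, `resname`,
#'   `aa1`, an `atoms` data frame (`name`, `element`, `altloc`, `occupancy`,
#'   `x`, `y`, `z`, `b`, `is_backbone`), the distinct non-blank `altlocs`,
#'   `n_conformers` (>= 1) and `n_unique_atoms` (unique heavy-atom names).
#' @examples
#' spec <- fixture_spec(n_residues = 8, seed = 1)
#' pdb <- file.path(tempdir(), "toy.pdb")
#' write_multiconformer_model(generate_structure(spec)$structure, pdb)
#' s <- read_multiconformer_model(pdb)
#' length(s$residues)
#' @export
read_multiconformer_model <- function(path, keep_chains = NULL,
                                      structure_id = NULL) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  pdb <- tryCatch(
    bio3d::read.pdb(path, rm.alt = FALSE, verbose = FALSE),
    error = function(e) stop("failed to parse PDB file '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  at <- pdb$atom
  for (col in c("alt", "insert", "elesy", "chain")) {
    at[[col]][is.na(at[[col]])] <- ""
  }
  at$o[is.na(at$o)] <- 1
  at$b[is.na(at$b)] <- 0

  protein <- at$resid %in% names(AA3TO1)
  dropped <- unique(at$resid[!protein & at$type == "ATOM" & at$resid != "HOH"])
  if (length(dropped) > 0) {
    warning("dropping non-standard residue(s): ",
            paste(dropped, collapse = ", "), call. = FALSE)
  }
  at <- at[protein, , drop = FALSE]

  elem <- at$elesy
  blank <- elem == ""
  # fall back on the atom name when the element column is absent
  elem[blank] <- substr(gsub("^[0-9]+", "", at$elety[blank]), 1, 1)
  at <- at[!(toupper(elem) %in% c("H", "D")), , drop = FALSE]
  elem <- elem[!(toupper(elem) %in% c("H", "D"))]

  if (!is.null(keep_chains)) {
    keep <- at$chain %in% keep_chains
    elem <- elem[keep]
    at <- at[keep, , drop = FALSE]
  }
  if (nrow(at) == 0) {
    stop("no protein residues found in '", path, "'", call. = FALSE)
  }

  rk <- res_key(at$chain, at$resno, at$insert)
  ord <- order(at$chain, at$resno, at$insert)
  at <- at[ord, , drop = FALSE]
  elem <- elem[ord]
  rk <- rk[ord]

  residues <- vector("list", length(unique(rk)))
  names(residues) <- unique(rk)
  idx <- split(seq_len(nrow(at)), factor(rk, levels = unique(rk)))
  for (key in names(idx)) {
    rows <- idx[[key]]
    sub <- at[rows, , drop = FALSE]
    atoms <- data.frame(
      name = sub$elety,
      element = toupper(elem[rows]),
      altloc = sub$alt,
      occupancy = sub$o,
      x = sub$x, y = sub$y, z = sub$z,
      b = sub$b,
      is_backbone = sub$elety %in% BACKBONE_ATOMS,
      stringsAsFactors = FALSE
    )
    altlocs <- sort(unique(atoms$altloc[atoms$altloc != ""]))
    if (length(altlocs) > 0) {
      occ_sum <- sum(vapply(
        altlocs,
        function(a) mean(atoms$occupancy[atoms$altloc == a]),
        numeric(1)
      ))
      if (occ_sum <= 0 || occ_sum > 1.02) {
        warning("residue ", key, ": conformer occupancies sum to ",
                signif(occ_sum, 4), " (expected in (0, 1.02])", call. = FALSE)
      }
    }
    residues[[key]] <- list(
      chain = sub$chain[1], resno = sub$resno[1], icode = sub$insert[1],
      key = key, resname = sub$resid[1],
      aa1 = unname(AA3TO1[sub$resid[1]]),
      atoms = atoms,
      altlocs = altlocs,
      n_conformers = max(1L, length(altlocs)),
      n_unique_atoms = length(unique(atoms$name))
    )
  }

  structure(list(
    structure_id = structure_id %||% tools::file_path_sans_ext(basename(path)),
    resolution = .parse_resolution(path),
    chains = sort(unique(at$chain)),
    residues = residues
  ), class = "mc_structure")
}

.parse_resolution <- function(path) {
  hdr <- grep("^REMARK   2 RESOLUTION", readLines(path, warn = FALSE),
              value = TRUE)
  if (length(hdr) == 0) return(NA_real_)
  m <- regmatches(hdr[1], regexpr("[0-9]+\\.[0-9]+", hdr[1]))
  if (length(m) == 0) NA_real_ else as.numeric(m)
}

#' Atoms of one conformer of a residue
#'
#' Returns the atoms belonging to the named conformer: those carrying its
#' altloc label plus the blank-altloc atoms shared by all conformers of the
#' residue.
#'
#' @param residue a residue record from an `mc_structure`.
#' @param label a one-character altloc label (must be one of
#'   `residue$altlocs`, unless the residue is single-conformer).
#' @return the conformer's atom data frame.
#' @export
conformer_atoms <- function(residue, label = "") {
  if (label != "" && !label %in% residue$altlocs) {
    stop("residue ", residue$key, " has no conformer '", label, "'",
         call. = FALSE)
  }
  residue$atoms[residue$atoms$altloc %in% c("", label), , drop = FALSE]
}

#' @export
print.mc_structure <- function(x, ...) {
  cat("Multiconformer structure", x$structure_id, "\n")
  cat("  chains:", paste(x$chains, collapse = ", "),
      " residues:", length(x$residues),
      " resolution:", x$resolution, "A\n")
  invisible(x)
}

#' Split a structure into single-chain instances
#'
#' Structures with several copies of the molecule in the asymmetric unit
#' (non-crystallographic symmetry) are split into one structure per protein
#' chain so that each copy contributes an independent network. IDs are
#' suffixed with the chain ID; output order is chain-ID ascending.
#'
#' @param structure an `mc_structure`.
#' @return list of single-chain `mc_structure` objects.
#' @export
split_single_chain_instances <- function(structure) {
  stopifnot(inherits(structure, "mc_structure"))
  chains <- sort(structure$chains)
  lapply(chains, function(ch) {
    keep <- vapply(structure$residues, function(r) r$chain == ch, logical(1))
    structure(list(
      structure_id = paste0(structure$structure_id, "_", ch),
      resolution = structure$resolution,
      chains = ch,
      residues = structure$residues[keep]
    ), class = "mc_structure")
  })
}

#' Read a structure metadata table
#'
#' Reads a CSV/TSV table (header row required) of per-structure metadata:
#' `structure_id` (required, unique), and optionally `protein_name`,
#' `resolution` (Angstrom), `wpd_state` (open/closed/other/unknown) and
#' `ligand_class` (apo/active_site/allosteric/other). Categorical values are
#' case-folded; unrecognized values map to `unknown` (`wpd_state`) or `other`
#' (`ligand_class`) with a warning. Extra columns are carried through as
#' free-form tags.
#'
#' @param path path to a delimited text file; tab-separated if the extension
#'   is `.tsv` or the header contains tabs, comma-separated otherwise.
#' @return data frame of metadata, one row per structure.
#' @export
read_metadata_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first) || grepl("\\.tsv$", path)) "\t" else ","
  md <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  if (!"structure_id" %in% names(md)) {
    stop("metadata table lacks required column 'structure_id'", call. = FALSE)
  }
  dup <- md$structure_id[duplicated(md$structure_id)]
  if (length(dup) > 0) {
    stop("duplicated structure_id in metadata: ",
         paste(unique(dup), collapse = ", "), call. = FALSE)
  }
  md$structure_id <- as.character(md$structure_id)

  md$wpd_state <- .fold_category(
    if ("wpd_state" %in% names(md)) md$wpd_state else NA,
    allowed = c("open", "closed", "other", "unknown"),
    fallback = "unknown", column = "wpd_state", n = nrow(md)
  )
  md$ligand_class <- .fold_category(
    if ("ligand_class" %in% names(md)) md$ligand_class else NA,
    allowed = c("apo", "active_site", "allosteric", "other"),
    fallback = "other", column = "ligand_class", n = nrow(md)
  )
  if (!"protein_name" %in% names(md)) md$protein_name <- NA_character_
  if ("resolution" %in% names(md)) {
    md$resolution <- as.numeric(md$resolution)
    if (any(!is.na(md$resolution) & md$resolution <= 0)) {
      warning("non-positive resolution values in metadata", call. = FALSE)
    }
  } else {
    md$resolution <- NA_real_
  }
  md
}

.fold_category <- function(x, allowed, fallback, column, n) {
  x <- tolower(trimws(as.character(rep_len(x, n))))
  x[is.na(x) | x == "" | x == "na"] <- fallback
  bad <- !(x %in% allowed)
  if (any(bad)) {
    warning("unknown ", column, " value(s) ",
            paste(unique(x[bad]), collapse = ", "),
            " mapped to '", fallback, "'", call. = FALSE)
    x[bad] <- fallback
  }
  x
}

#' Conformer counts per residue
#'
#' Mean number of alternate conformations per residue, per structure and
#' globally (residue-weighted: the global mean is the mean over all residues
#' pooled across structures).
#'
#' @param structures list of `mc_structure` objects.
#' @return list with `per_structure` (named numeric), `global` (numeric) and
#'   `n_residues` (total residues pooled).
#' @export
conformer_stats <- function(structures) {
  if (inherits(structures, "mc_structure")) structures <- list(structures)
  stopifnot(length(structures) >= 1)
  counts <- lapply(structures, function(s) {
    vapply(s$residues, function(r) r$n_conformers, numeric(1))
  })
  per <- vapply(counts, mean, numeric(1))
  names(per) <- vapply(structures, function(s) s$structure_id, character(1))
  all_counts <- unlist(counts, use.names = FALSE)
  list(per_structure = per, global = mean(all_counts),
       n_residues = length(all_counts))
}

#' Write a multiconformer structure as PDB
#'
#' Serializes the internal model back to PDB (standard columns, 3-decimal
#' coordinates, altloc column 17). The `b` column of the atom tables is
#' written to the B-factor field.
#'
#' @param structure an `mc_structure`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_multiconformer_model <- function(structure, path) {
  stopifnot(inherits(structure, "mc_structure"))
  rows <- do.call(rbind, lapply(structure$residues, function(r) {
    cbind(r$atoms,
          chain = r$chain, resno = r$resno, insert = r$icode,
          resid = r$resname, stringsAsFactors = FALSE)
  }))
  n <- nrow(rows)
  alt <- rows$altloc
  alt[alt == ""] <- ""
  bio3d::write.pdb(
    file = path,
    xyz = as.numeric(t(as.matrix(rows[, c("x", "y", "z")]))),
    type = rep("ATOM", n),
    resno = rows$resno,
    resid = rows$resid,
    eleno = seq_len(n),
    elety = rows$name,
    chain = rows$chain,
    insert = rows$insert,
    alt = alt,
    o = rows$occupancy,
    b = rows$b,
    elesy = rows$element
  )
  invisible(path)
}
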