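# Synthetic multiconformer structures with known ground-truth networks.
#
# Geometry: residues sit on an extended chain with 6 A spacing, so that
# sequence-adjacent backbones are in peptide-bond contact while residues two
# or more positions apart are > 6 A from each other. Long-range planted
# contacts are realized by altloc "stub" atoms placed in well-separated
# lanes above the chain, guaranteeing that non-planted residue pairs stay
# beyond cutoff + 2 A. Realism is not a goal; exact distance bookkeeping,
# altloc assembly and PDB round-tripping are.

.STUB_NAMES <- c("CG", "CD", "CE", "CZ", "CX", "CY")

#' Specification for synthetic multiconformer fixtures
#'
#' @param n_residues residues per structure.
#' @param planted_contacts data frame with integer columns `i`, `j` (residue
#'   positions, `j > i + 1`) of long-range contacts to realize between
#'   alternate-conformation atoms.
#' @param backbone_runs list of integer vectors of consecutive residue
#'   positions whose backbone atoms get two alternate conformations.
#' @param n_structures number of structures for [generate_family()].
#' @param displacement altloc B = altloc A + a displacement of this magnitude
#'   in Angstrom (default 1.0, the scale of qFit alternate conformations).
#' @param noise_sd per-coordinate Gaussian noise in Angstrom (default 0).
#' @param seed integer seed (mandatory).
#' @return list of class `fixture_spec`.
#' @export
fixture_spec <- function(n_residues = 30,
                         planted_contacts = NULL,
                         backbone_runs = list(),
                         n_structures = 10,
                         displacement = 1.0,
                         noise_sd = 0,
                         seed) {
  if (missing(seed)) stop("fixture_spec requires an explicit seed",
                          call. = FALSE)
  if (is.null(planted_contacts)) {
    planted_contacts <- data.frame(i = integer(), j = integer())
  }
  stopifnot(n_residues >= 4, displacement > 0, noise_sd >= 0)
  if (nrow(planted_contacts) > 0) {
    with(planted_contacts, stopifnot(all(i >= 1), all(j <= n_residues),
                                     all(j - i > 1)))
  }
  for (run in backbone_runs) {
    stopifnot(all(diff(run) == 1), min(run) >= 1, max(run) <= n_residues)
  }
  structure(list(n_residues = n_residues,
                 planted_contacts = planted_contacts,
                 backbone_runs = backbone_runs,
                 n_structures = n_structures,
                 displacement = displacement,
                 noise_sd = noise_sd,
                 seed = seed),
            class = "fixture_spec")
}

# deterministic pseudo-random residue names (no GLY: every residue carries a
# CB stub; no MSE: keeps one-letter mapping unambiguous in toy MSAs)
.random_resnames <- function(n, seed) {
  pool <- setdiff(names(AA3TO1), c("GLY", "MSE"))
  .with_seed(seed, sample(pool, n, replace = TRUE))
}

.build_structure <- function(structure_id, n_res, resnames, contacts, runs,
                             displacement, noise_sd, rng_seed) {
  spacing <- 6.0
  base_offsets <- list(N = c(-1.7, 0, 0), CA = c(0, 0, 0), C = c(1.7, 0, 0),
                       O = c(1.7, 1.2, 0), CB = c(0, -1.5, 0))
  run_members <- unique(unlist(runs))

  rows <- vector("list", n_res)
  for (k in seq_len(n_res)) {
    ctr <- c(spacing * k, 0, 0)
    recs <- list()
    for (nm in names(base_offsets)) {
      pos <- ctr + base_offsets[[nm]]
      bb <- nm %in% BACKBONE_ATOMS
      if (bb && k %in% run_members) {
        recs[[length(recs) + 1]] <- data.frame(
          name = nm, element = substr(nm, 1, 1),
          altloc = c("A", "B"), occupancy = 0.5,
          x = c(pos[1], pos[1]), y = c(pos[2], pos[2]),
          z = c(pos[3], pos[3] + displacement),
          b = 0, is_backbone = bb, stringsAsFactors = FALSE)
      } else {
        recs[[length(recs) + 1]] <- data.frame(
          name = nm, element = substr(nm, 1, 1),
          altloc = "", occupancy = 1,
          x = pos[1], y = pos[2], z = pos[3],
          b = 0, is_backbone = bb, stringsAsFactors = FALSE)
      }
    }
    rows[[k]] <- do.call(rbind, recs)
  }

  stub_count <- integer(n_res)
  if (nrow(contacts) > 0) {
    for (p in seq_len(nrow(contacts))) {
      i <- contacts$i[p]
      j <- contacts$j[p]
      lane_y <- 12 + 9 * (p - 1)
      m <- c(spacing * (i + j) / 2, lane_y, 0)
      for (side in c(1, 2)) {
        k <- if (side == 1) i else j
        dx <- if (side == 1) -0.7 else 0.7
        stub_count[k] <- stub_count[k] + 1L
        if (stub_count[k] > length(.STUB_NAMES)) {
          stop("infeasible geometry: residue ", k,
               " participates in too many planted contacts", call. = FALSE)
        }
        nm <- .STUB_NAMES[stub_count[k]]
        a_pos <- m + c(dx, -0.5, 0)
        rows[[k]] <- rbind(rows[[k]], data.frame(
          name = nm, element = "C",
          altloc = c("A", "B"), occupancy = 0.5,
          x = a_pos[1], y = c(a_pos[2], a_pos[2] + displacement),
          z = a_pos[3],
          b = 0, is_backbone = FALSE, stringsAsFactors = FALSE))
      }
    }
  }

  if (noise_sd > 0) {
    rows <- .with_seed(rng_seed, lapply(rows, function(df) {
      df$x <- df$x + stats::rnorm(nrow(df), 0, noise_sd)
      df$y <- df$y + stats::rnorm(nrow(df), 0, noise_sd)
      df$z <- df$z + stats::rnorm(nrow(df), 0, noise_sd)
      df
    }))
  }

  residues <- vector("list", n_res)
  keys <- res_key("A", seq_len(n_res))
  names(residues) <- keys
  for (k in seq_len(n_res)) {
    atoms <- rows[[k]]
    rownames(atoms) <- NULL
    altlocs <- sort(unique(atoms$altloc[atoms$altloc != ""]))
    residues[[k]] <- list(
      chain = "A", resno = k, icode = "", key = keys[k],
      resname = resnames[k], aa1 = unname(AA3TO1[resnames[k]]),
      atoms = atoms, altlocs = altlocs,
      n_conformers = max(1L, length(altlocs)),
      n_unique_atoms = length(unique(atoms$name))
    )
  }
  structure(list(structure_id = structure_id, resolution = NA_real_,
                 chains = "A", residues = residues),
            class = "mc_structure")
}

.truth_edges <- function(n_res, contacts, runs) {
  spatial <- if (nrow(contacts) > 0) {
    data.frame(i = res_key("A", contacts$i), j = res_key("A", contacts$j),
               provenance = "spatial", stringsAsFactors = FALSE)
  } else {
    data.frame(i = character(), j = character(), provenance = character())
  }
  seq_rows <- do.call(rbind, lapply(runs, function(run) {
    if (length(run) < 2) return(NULL)
    data.frame(i = res_key("A", run[-length(run)]),
               j = res_key("A", run[-1]),
               provenance = "sequential", stringsAsFactors = FALSE)
  }))
  rbind(spatial, seq_rows)
}

#' Generate one synthetic multiconformer structure
#'
#' Realizes the planted contacts and backbone-altloc runs of a
#' [fixture_spec()] as a parseable structure: planted pairs have altloc atoms
#' within the 4 A contact cutoff, all other non-adjacent residue pairs stay
#' beyond cutoff + 2 A, and sequence-adjacent backbones are in peptide-bond
#' contact. Deterministic for a fixed spec seed and index.
#'
#' @param spec a [fixture_spec()].
#' @param index structure index (varies the noise stream per structure).
#' @param structure_id defaults to `sprintf("syn%02d", index)`.
#' @return list with `structure` (an `mc_structure`) and `truth` (data frame
#'   of ground-truth edges `i`, `j`, `provenance`).
#' @export
generate_structure <- function(spec, index = 1, structure_id = NULL) {
  stopifnot(inherits(spec, "fixture_spec"))
  structure_id <- structure_id %||% sprintf("syn%02d", index)
  resnames <- .random_resnames(spec$n_residues, spec$seed)
  st <- .build_structure(structure_id, spec$n_residues, resnames,
                         spec$planted_contacts, spec$backbone_runs,
                         spec$displacement, spec$noise_sd,
                         rng_seed = spec$seed + 1000L * index + 17L)
  list(structure = st,
       truth = .truth_edges(spec$n_residues, spec$planted_contacts,
                            spec$backbone_runs))
}

#' Generate a family of related synthetic structures with MSA and metadata
#'
#' Generates `spec$n_structures` structures sharing a core sequence (with one
#' deterministic point substitution per structure) and the spec's planted
#' contacts and backbone runs; writes/returns an aligned FASTA and a metadata
#' table splitting the family into subsets A (`wpd_state = "closed"`) and B
#' (`"open"`). When `subset_effect` is given, that extra contact is planted
#' only in subset A structures, creating a known degree difference at its two
#' residues. Each structure additionally carries per-structure "decoy"
#' contacts, unique across the family, so that shared edges dominate the sum
#' network: the number of distinct decoy edges is chosen such that the top
#' 20% of sum-network edges is exactly the shared planted set. One structure
#' (the second, when `include_insertion`) carries a one-residue insertion to
#' exercise alignment-gap handling.
#'
#' @param spec a [fixture_spec()].
#' @param dir optional directory; when given, PDB files, `alignment.fasta`
#'   and `metadata.csv` are written there.
#' @param subset_effect optional `c(i, j)` positions of a subset-A-only
#'   contact.
#' @param include_insertion plant a one-residue insertion in structure 2.
#' @return list with `structures`, `truths` (per structure), `shared_truth`,
#'   `alignment` (an `msa`), `metadata`, `maps` (per-structure
#'   `alignment_map`s), `reference_id`, `subset_a`, `subset_b`, and the file
#'   `paths` when `dir` was given.
#' @export
generate_family <- function(spec, dir = NULL, subset_effect = NULL,
                            include_insertion = TRUE) {
  stopifnot(inherits(spec, "fixture_spec"), spec$n_structures >= 2)
  n_str <- spec$n_structures
  n_res <- spec$n_residues
  ids <- sprintf("syn%02d", seq_len(n_str))
  subset_a <- ids[seq_len(floor(n_str / 2))]
  subset_b <- setdiff(ids, subset_a)

  core_res <- .random_resnames(n_res, spec$seed)
  n_truth <- nrow(spec$planted_contacts) +
    sum(vapply(spec$backbone_runs, function(r) max(0, length(r) - 1),
               numeric(1)))

  # decoy pool: distinct non-adjacent pairs, disjoint from planted pairs,
  # sized so ceiling(0.2 * (n_truth [+1 effect] + n_decoys)) == n_truth
  fam <- .with_seed(spec$seed + 99L, {
    planted_key <- paste(spec$planted_contacts$i, spec$planted_contacts$j)
    if (!is.null(subset_effect)) {
      planted_key <- c(planted_key, paste(subset_effect[1], subset_effect[2]))
    }
    run_members <- unique(unlist(spec$backbone_runs))
    cand <- expand.grid(i = seq_len(n_res), j = seq_len(n_res))
    cand <- cand[cand$j - cand$i > 1, ]
    cand <- cand[!(paste(cand$i, cand$j) %in% planted_key), ]
    cand <- cand[!(cand$i %in% run_members) & !(cand$j %in% run_members), ]
    n_decoys <- 4L * n_truth
    if (n_decoys > nrow(cand)) {
      stop("infeasible geometry: not enough residue pairs for decoys",
           call. = FALSE)
    }
    pool <- cand[sample(nrow(cand), n_decoys), , drop = FALSE]
    owner <- rep(seq_len(n_str), length.out = n_decoys)
    subs_pos <- sample(n_res, n_str, replace = TRUE)
    subs_aa <- sample(setdiff(names(AA3TO1), c("GLY", "MSE")), n_str,
                      replace = TRUE)
    resolutions <- round(stats::runif(n_str, 1.2, 2.0), 2)
    list(pool = pool, owner = owner, subs_pos = subs_pos,
         subs_aa = subs_aa, resolutions = resolutions)
  })

  ins_pos <- if (include_insertion) floor(n_res / 2) else NA_integer_
  ins_id <- if (include_insertion) ids[2] else NA_character_

  structures <- list()
  truths <- list()
  msa_rows <- character(n_str)
  for (s in seq_len(n_str)) {
    id <- ids[s]
    resnames <- core_res
    if (fam$subs_aa[s] != resnames[fam$subs_pos[s]]) {
      resnames[fam$subs_pos[s]] <- fam$subs_aa[s]
    }
    contacts <- spec$planted_contacts
    if (!is.null(subset_effect) && id %in% subset_a) {
      contacts <- rbind(contacts,
                        data.frame(i = subset_effect[1], j = subset_effect[2]))
    }
    decoys <- fam$pool[fam$owner == s, , drop = FALSE]
    contacts <- rbind(contacts, decoys)
    runs <- spec$backbone_runs
    n_here <- n_res

    shift <- function(pos) pos  # identity unless insertion applies
    if (identical(id, ins_id)) {
      # insert one residue after ins_pos; later positions shift by one
      n_here <- n_res + 1L
      ins_name <- "ALA"
      resnames <- append(resnames, ins_name, after = ins_pos)
      shift <- function(pos) ifelse(pos > ins_pos, pos + 1L, pos)
      contacts$i <- shift(contacts$i)
      contacts$j <- shift(contacts$j)
      runs <- lapply(runs, shift)
    }
    st <- .build_structure(id, n_here, resnames, contacts, runs,
                           spec$displacement, spec$noise_sd,
                           rng_seed = spec$seed + 1000L * s + 17L)
    structures[[id]] <- st
    truths[[id]] <- .truth_edges(n_here, contacts, runs)

    aa <- vapply(st$residues, function(r) r$aa1, character(1))
    row <- character(n_res + as.integer(include_insertion))
    if (identical(id, ins_id)) {
      row <- aa
    } else if (include_insertion) {
      row <- append(aa, "-", after = ins_pos)
    } else {
      row <- aa
    }
    msa_rows[s] <- paste(row, collapse = "")
  }

  alignment <- structure(list(ids = ids,
                              seqs = stats::setNames(msa_rows, ids),
                              n_columns = nchar(msa_rows[1])),
                         class = "msa")
  metadata <- data.frame(
    structure_id = ids,
    protein_name = "SYN",
    resolution = fam$resolutions,
    wpd_state = ifelse(ids %in% subset_a, "closed", "open"),
    ligand_class = "apo",
    stringsAsFactors = FALSE
  )
  maps <- lapply(ids, function(id) {
    build_residue_map(alignment, id, structures[[id]], reference_id = ids[1])
  })
  names(maps) <- ids

  shared_truth <- .truth_edges(n_res, spec$planted_contacts,
                               spec$backbone_runs)

  paths <- NULL
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    pdbs <- file.path(dir, paste0(ids, ".pdb"))
    for (s in seq_len(n_str)) {
      write_multiconformer_model(structures[[ids[s]]], pdbs[s])
    }
    fa <- file.path(dir, "alignment.fasta")
    writeLines(paste0(">", ids, "\n", msa_rows), fa)
    meta_csv <- file.path(dir, "metadata.csv")
    utils::write.csv(metadata, meta_csv, row.names = FALSE, quote = FALSE)
    paths <- list(pdb = pdbs, alignment = fa, metadata = meta_csv)
  }

  list(structures = structures, truths = truths, shared_truth = shared_truth,
       alignment = alignment, metadata = metadata, maps = maps,
       reference_id = ids[1], subset_a = subset_a, subset_b = subset_b,
       subset_effect = subset_effect, paths = paths)
}
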