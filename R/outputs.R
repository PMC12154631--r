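# Writers and pipeline orchestration.

#' Write a network as a TSV edge list or GraphML
#'
#' Edge lists are written in canonical order (lower endpoint first, rows
#' sorted); GraphML carries the `weight` (and, for per-structure networks,
#' `provenance`) edge attributes.
#'
#' @param net a `residue_rin` or `sum_network`.
#' @param path output file path.
#' @param format `"tsv_edges"` or `"graphml"`.
#' @return `path`, invisibly.
#' @export
write_network <- function(net, path, format = c("tsv_edges", "graphml")) {
  format <- match.arg(format)
  edges <- net$edges
  if (nrow(edges) > 0) {
    ord <- order(as.character(edges$i), as.character(edges$j),
                 method = "radix")
    suppressWarnings({
      ni <- as.numeric(as.character(edges$i))
      nj <- as.numeric(as.character(edges$j))
    })
    if (!anyNA(ni) && !anyNA(nj)) ord <- order(ni, nj)
    edges <- edges[ord, , drop = FALSE]
    rownames(edges) <- NULL
  }
  if (format == "tsv_edges") {
    utils::write.table(edges, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else {
    g <- igraph::graph_from_data_frame(
      cbind(data.frame(from = as.character(edges$i),
                       to = as.character(edges$j)),
            edges[, setdiff(names(edges), c("i", "j")), drop = FALSE]),
      directed = FALSE, vertices = as.character(net$nodes))
    igraph::write_graph(g, path, format = "graphml")
  }
  invisible(path)
}

#' Read a GraphML network back as an edge table
#'
#' @param path a GraphML file written by [write_network()].
#' @return list with `nodes` (character) and `edges` (data frame `i`, `j`,
#'   `weight`, plus any further edge attributes).
#' @export
read_network_graphml <- function(path) {
  g <- igraph::read_graph(path, format = "graphml")
  el <- igraph::as_data_frame(g, what = "edges")
  names(el)[1:2] <- c("i", "j")
  list(nodes = igraph::V(g)$name, edges = el)
}

#' Write a per-residue profile as TSV
#'
#' @param profile a `delta_degree` data frame or a named numeric vector
#'   (names taken as reference residue numbers).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_profile <- function(profile, path) {
  df <- if (is.data.frame(profile)) {
    profile
  } else {
    data.frame(ref_resno = names(profile), value = unname(profile))
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Map per-residue values onto a structure's B-factor field
#'
#' Writes a copy of the structure with the given per-reference-residue value
#' in the B-factor column of every atom of mapped residues (unmapped residues
#' get the sentinel), plus a per-residue TSV next to it. This supports
#' sphere/putty rendering of network degree on a representative structure in
#' any molecular viewer. Values outside the PDB field range
#' `[-99.99, 999.99]` are clamped with a warning.
#'
#' @param structure an `mc_structure`.
#' @param values named numeric vector (reference residue number -> value).
#' @param path output PDB path (the TSV is written to `<path>.tsv`).
#' @param map optional `alignment_map` giving the structure's reference
#'   numbering; author numbering is used by default.
#' @param sentinel B-factor for unmapped residues (default -1).
#' @return `path`, invisibly.
#' @export
write_structure_attribute <- function(structure, values, path, map = NULL,
                                      sentinel = -1) {
  stopifnot(inherits(structure, "mc_structure"))
  res <- structure$residues
  refno <- if (is.null(map)) {
    vapply(res, function(r) as.integer(r$resno), integer(1))
  } else {
    as.integer(map$ref_of_col[map$col_of_res[names(res)]])
  }
  hit <- !is.na(refno) & as.character(refno) %in% names(values)
  if (!any(hit)) stop("no residues map onto the supplied values",
                      call. = FALSE)
  v <- rep(sentinel, length(res))
  v[hit] <- unname(values[as.character(refno[hit])])
  if (any(v > 999.99 | v < -99.99)) {
    warning("attribute values clamped to the PDB B-factor field range",
            call. = FALSE)
    v <- pmin(pmax(v, -99.99), 999.99)
  }
  for (k in seq_along(res)) {
    structure$residues[[k]]$atoms$b <- v[k]
  }
  write_multiconformer_model(structure, path)
  utils::write.table(
    data.frame(ref_resno = refno, residue = names(res), value = v),
    paste0(path, ".tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# subset definition over the metadata table: column=values and/or numeric
# min/max clauses
.subset_ids_from_def <- function(md, def) {
  stopifnot(!is.null(def$column), def$column %in% names(md))
  x <- md[[def$column]]
  keep <- rep(TRUE, nrow(md))
  if (!is.null(def$values)) keep <- keep & x %in% def$values
  if (!is.null(def$min)) keep <- keep & !is.na(x) & x >= def$min
  if (!is.null(def$max)) keep <- keep & !is.na(x) & x <= def$max
  md$structure_id[keep]
}

#' Run the full network pipeline from a configuration
#'
#' Executes parse -> build -> align -> normalize -> multinetwork -> requested
#' analyses, writing all artifacts and a machine-readable JSON run report.
#' Idempotent for a fixed configuration and seed.
#'
#' The configuration is a named list (or the path of a YAML file with the
#' same structure) with entries:
#' \describe{
#'   \item{structures_dir}{directory of multiconformer PDB files.}
#'   \item{msa}{aligned FASTA/CLUSTAL file; row IDs must match structure
#'     IDs.}
#'   \item{metadata}{metadata CSV/TSV (optional).}
#'   \item{reference_id}{MSA row used as the reference numbering.}
#'   \item{contact_cutoff, min_conformers}{network parameters (4.0, 2).}
#'   \item{trim_keep}{fraction of edges kept in the pruned sum network
#'     (default 0.05).}
#'   \item{average}{per-structure averaging for subset comparisons
#'     (default TRUE).}
#'   \item{subsets}{named list of subset definitions
#'     (`list(column=, values=)` and/or `min`/`max`).}
#'   \item{comparisons}{list of `list(a = <subset name>, b = <subset name>)`
#'     degree-difference contrasts.}
#'   \item{random_half}{number of random-half control samples (optional).}
#'   \item{communities}{run community detection on the pruned sum network
#'     (default TRUE).}
#'   \item{seed}{integer seed for stochastic stages.}
#'   \item{out_dir}{output directory.}
#' }
#'
#' @param config named list or YAML file path.
#' @return the run report, invisibly (also written to
#'   `out_dir/run_report.json`).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("reading YAML configs requires the 'yaml' package", call. = FALSE)
    }
    config <- yaml::read_yaml(config)
  }
  for (field in c("structures_dir", "msa", "reference_id", "out_dir")) {
    if (is.null(config[[field]])) {
      stop("config lacks required field '", field, "'", call. = FALSE)
    }
  }
  for (p in c(config$structures_dir, config$msa, config$metadata)) {
    if (!is.null(p) && !file.exists(p)) {
      stop("config path does not exist: ", p, call. = FALSE)
    }
  }
  out_dir <- config$out_dir
  dir.create(file.path(out_dir, "networks"), recursive = TRUE,
             showWarnings = FALSE)
  warnings_log <- character()
  log_warning <- function(w) {
    warnings_log <<- c(warnings_log, conditionMessage(w))
    invokeRestart("muffleWarning")
  }

  params <- rin_params(
    contact_cutoff = config$contact_cutoff %||% 4.0,
    min_conformers = config$min_conformers %||% 2L)
  trim_keep <- config$trim_keep %||% 0.05
  seed <- config$seed %||% 1L

  report <- list(package_version = as.character(
    utils::packageVersion("altrin")),
    parameters = list(contact_cutoff = params$contact_cutoff,
                      min_conformers = params$min_conformers,
                      trim_keep = trim_keep, seed = seed),
    files = character())
  add_file <- function(p) report$files <<- c(report$files, p)

  withCallingHandlers({
    paths <- sort(list.files(config$structures_dir, pattern = "\\.pdb$",
                             full.names = TRUE))
    if (length(paths) == 0) {
      stop("no PDB files in ", config$structures_dir, call. = FALSE)
    }
    structures <- list()
    for (p in paths) {
      st <- read_multiconformer_model(p)
      pieces <- if (length(st$chains) > 1) {
        split_single_chain_instances(st)
      } else {
        list(st)
      }
      for (piece in pieces) structures[[piece$structure_id]] <- piece
    }

    rins <- lapply(structures, build_network, params = params)
    for (id in names(rins)) {
      f <- file.path(out_dir, "networks", paste0(id, "_edges.tsv"))
      write_network(rins[[id]], f)
      add_file(f)
    }

    aln <- read_alignment(config$msa)
    metadata <- if (!is.null(config$metadata)) {
      read_metadata_table(config$metadata)
    } else {
      NULL
    }
    present <- intersect(names(structures), aln$ids)
    absent <- setdiff(names(structures), aln$ids)
    if (length(absent) > 0) {
      warning("structures absent from the MSA skipped: ",
              paste(absent, collapse = ", "), call. = FALSE)
    }
    if (length(present) == 0) {
      stop("no structure has an MSA row; check IDs", call. = FALSE)
    }
    maps <- lapply(present, function(id) {
      build_residue_map(aln, id, structures[[id]], config$reference_id)
    })
    names(maps) <- present
    aligned <- lapply(present, function(id) {
      log_normalize(align_rin(rins[[id]], maps[[id]]))
    })
    mn <- build_multinetwork(aligned, metadata,
                             ref_of_col = maps[[1]]$ref_of_col)

    full_sum <- sum_network(mn)
    f <- file.path(out_dir, "sum_network.tsv")
    write_network(full_sum, f); add_file(f)
    trimmed <- trim_top_fraction(full_sum, trim_keep)
    f <- file.path(out_dir, "sum_network_trimmed.tsv")
    write_network(trimmed, f); add_file(f)
    deg <- weighted_degree(full_sum, nodes = seq_len(mn$n_columns))
    names(deg) <- ifelse(is.na(mn$ref_of_col), names(deg),
                         mn$ref_of_col)
    f <- file.path(out_dir, "degree.tsv")
    write_profile(deg, f); add_file(f)

    report$n_structures <- length(structures)
    report$n_networks <- length(aligned)
    report$n_dropped_edges <- sum(vapply(aligned, function(a) a$n_dropped,
                                         numeric(1)))
    report$sum_network <- list(nodes = length(full_sum$nodes),
                               edges = nrow(full_sum$edges))
    report$trimmed_network <- list(nodes = length(trimmed$nodes),
                                   edges = nrow(trimmed$edges))

    if (isTRUE(config$communities %||% TRUE) && nrow(trimmed$edges) > 0) {
      cp <- girvan_newman(trimmed)
      f <- file.path(out_dir, "communities.tsv")
      utils::write.table(
        data.frame(column = names(cp$membership),
                   community = unname(cp$membership)),
        f, sep = "\t", quote = FALSE, row.names = FALSE)
      add_file(f)
      f <- file.path(out_dir, "modularity_trace.tsv")
      utils::write.table(cp$trace, f, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      add_file(f)
      report$communities <- list(n = cp$n_communities,
                                 modularity = cp$modularity)
    }

    subset_ids <- lapply(config$subsets %||% list(), function(def) {
      intersect(.subset_ids_from_def(mn$metadata, def), names(mn$networks))
    })
    for (cmp in config$comparisons %||% list()) {
      a <- subset_ids[[cmp$a]]
      b <- subset_ids[[cmp$b]]
      if (length(a) == 0 || length(b) == 0) {
        stop("comparison ", cmp$a, " vs ", cmp$b,
             ": a subset selects no structures", call. = FALSE)
      }
      d <- delta_degree(mn, a, b, label_a = cmp$a, label_b = cmp$b)
      f <- file.path(out_dir,
                     paste0("delta_degree_", cmp$a, "_vs_", cmp$b, ".tsv"))
      write_profile(d, f); add_file(f)
    }

    if (!is.null(config$random_half)) {
      ctrl <- random_half_control(mn, n_samples = config$random_half,
                                  seed = seed)
      f <- file.path(out_dir, "random_half_control.tsv")
      write_profile(ctrl, f); add_file(f)
      report$random_half <- list(n_samples = config$random_half,
                                 mean_abs_delta = mean(abs(ctrl$delta)))
    }
  }, warning = log_warning)

  report$warnings <- warnings_log
  jsonlite::write_json(report, file.path(out_dir, "run_report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(report)
}
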