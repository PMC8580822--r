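#' Pipeline configuration
#'
#' Bundles input locations and analysis parameters for [run_pipeline()].
#' All inputs are plain files: structures (mmCIF/PDB) in a directory,
#' residue-to-generic mapping TSVs next to them (`<id>_mapping.tsv`) or one
#' combined table, an annotation catalog TSV, a class alignment TSV
#' (`receptor`, `position`, `aa`, optionally `gpcr_class`) and a mutant
#' signaling TSV. Unknown stage names are rejected up front.
#'
#' @param output_dir directory for all outputs (created when missing).
#' @param structures_dir directory of structure files.
#' @param mapping_table optional combined mapping TSV (otherwise per-file
#'   `<id>_mapping.tsv` files are used).
#' @param annotation_catalog catalog TSV path or annotation tibble.
#' @param alignment alignment TSV path or tibble.
#' @param mutant_table mutant TSV path or tibble.
#' @param criteria a [selection_criteria()].
#' @param params a [contact_params()].
#' @param thresholds a [class_thresholds()].
#' @param regions a [region_spec()].
#' @param stages subset of `select`, `contacts`, `statemap`, `helixmove`,
#'   `mutstats`.
#' @param chain receptor chain identifier in the structure files.
#' @param seed integer seed recorded in output headers.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(output_dir,
                            structures_dir = NULL, mapping_table = NULL,
                            annotation_catalog = NULL, alignment = NULL,
                            mutant_table = NULL,
                            criteria = selection_criteria(),
                            params = contact_params(),
                            thresholds = class_thresholds(),
                            regions = region_spec(),
                            stages = c("select", "contacts", "statemap",
                                       "helixmove", "mutstats"),
                            chain = "A", seed = 1L) {
  known <- c("select", "contacts", "statemap", "helixmove", "mutstats")
  bad <- setdiff(stages, known)
  if (length(bad)) {
    rlang::abort(paste0("Unknown pipeline stage(s): ",
                        paste(bad, collapse = ", ")))
  }
  structure(list(
    output_dir = output_dir, structures_dir = structures_dir,
    mapping_table = mapping_table, annotation_catalog = annotation_catalog,
    alignment = alignment, mutant_table = mutant_table,
    criteria = criteria, params = params, thresholds = thresholds,
    regions = regions, stages = stages, chain = chain, seed = as.integer(seed)
  ), class = "pipeline_config")
}

validate_pipeline_inputs <- function(config) {
  need <- function(stage, what, value) {
    if (stage %in% config$stages && is.null(value)) {
      rlang::abort(paste0("Stage '", stage, "' requested but ", what,
                          " is not configured."))
    }
  }
  need("select", "annotation_catalog", config$annotation_catalog)
  need("contacts", "structures_dir", config$structures_dir)
  need("contacts", "annotation_catalog", config$annotation_catalog)
  if ("statemap" %in% config$stages &&
      !"contacts" %in% config$stages) {
    rlang::abort("Stage 'statemap' needs stage 'contacts' in the same run.")
  }
  if ("helixmove" %in% config$stages && is.null(config$structures_dir)) {
    rlang::abort("Stage 'helixmove' requested but structures_dir is not configured.")
  }
  need("statemap", "alignment", config$alignment)
  need("mutstats", "mutant_table", config$mutant_table)
  invisible(TRUE)
}

read_input <- function(x, reader) {
  if (is.null(x)) return(NULL)
  if (is.character(x) && length(x) == 1) reader(x) else tibble::as_tibble(x)
}

pipeline_header <- function(config, extra = NULL) {
  c(paste0("# gpcrstates ",
           as.character(utils::packageVersion("gpcrstates"))),
    paste0("# seed=", config$seed),
    paste0("# contact_", provenance_line(config$params)),
    if (!is.null(extra)) paste0("# ", extra))
}

write_table_with_header <- function(tab, path, config, extra = NULL) {
  writeLines(pipeline_header(config, extra), path)
  readr::write_tsv(tab, path, append = TRUE, col_names = TRUE)
  invisible(path)
}

#' Run the comparative structure-analysis pipeline
#'
#' Executes the requested stages in dependency order: representative
#' template selection, per-structure contact detection, class-wise
#' state-specific contact analysis (frequencies, thresholds, conservation,
#' determinant classification and segment networks), helix movement
#' measurement for receptors covered in both states, and mutant group
#' statistics. Missing inputs for a requested stage abort before any work.
#' All tabular outputs carry provenance headers; re-running with identical
#' config and inputs reproduces them byte-for-byte.
#'
#' @param config a [pipeline_config()].
#' @return a list bundle with elements per executed stage: `catalog`,
#'   `selection_summary`, `contact_sets`, `pair_frequencies`,
#'   `state_specific`, `determinants`, `segment_network`, `movements`,
#'   `consensus`, `mutation_stats`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  validate_pipeline_inputs(config)
  if (!dir.exists(config$output_dir)) {
    dir.create(config$output_dir, recursive = TRUE)
  }
  out <- list()
  rows <- read_input(config$annotation_catalog, load_annotation)

  if ("select" %in% config$stages) {
    catalog <- select_representatives(rows, config$criteria)
    out$catalog <- catalog
    out$selection_summary <- count_selection(catalog)
    write_table_with_header(catalog$representatives,
                            file.path(config$output_dir, "representatives.tsv"),
                            config)
    s <- out$selection_summary
    jsonlite::write_json(
      list(n_inactive = s$n_inactive, n_active_entries = s$n_active_entries,
           n_active_parents = s$n_active_parents,
           n_templates_used = s$n_templates_used, n_pairs = s$n_pairs,
           n_le_3p0 = s$n_le_3p0),
      file.path(config$output_dir, "selection_summary.json"),
      auto_unbox = TRUE, digits = NA
    )
  }

  structures <- list()
  if (any(c("contacts", "helixmove") %in% config$stages)) {
    reps <- out$catalog$representatives %||%
      select_representatives(rows, config$criteria)$representatives
    combined_map <- read_input(config$mapping_table, read_generic_mapping)
    for (i in seq_len(nrow(reps))) {
      id <- reps$structure_id[i]
      f <- c(file.path(config$structures_dir, paste0(id, ".cif")),
             file.path(config$structures_dir, paste0(id, ".pdb")))
      f <- f[file.exists(f)][1]
      if (is.na(f)) next
      s <- load_structure(f, chain = config$chain, structure_id = id)
      s$receptor <- reps$receptor[i]
      s$gpcr_class <- reps$gpcr_class[i]
      s$state <- reps$state[i]
      map <- combined_map %||% {
        mf <- file.path(config$structures_dir, paste0(id, "_mapping.tsv"))
        if (file.exists(mf)) read_generic_mapping(mf) else NULL
      }
      if (!is.null(map)) s <- apply_generic_numbers(s, map)
      structures[[id]] <- s
    }
    out$structures <- structures
  }

  if ("contacts" %in% config$stages) {
    out$contact_sets <- purrr::map(structures, detect_contacts,
                                   params = config$params)
    for (cs in out$contact_sets) {
      write_contact_tsv(cs, file.path(config$output_dir,
                                      paste0("contacts_", cs$structure_id,
                                             ".tsv")))
    }
  }

  if ("statemap" %in% config$stages) {
    aln <- read_input(config$alignment, function(p)
      readr::read_tsv(p, show_col_types = FALSE, comment = "#"))
    by_class <- split(structures,
                      vapply(structures, `[[`, "", "gpcr_class"))
    freqs <- list(); specific <- list(); dets <- list()
    for (cls in names(by_class)) {
      ss <- by_class[[cls]]
      states <- vapply(ss, `[[`, "", "state")
      if (!any(states == "inactive") || !any(states == "active")) next
      cs_i <- out$contact_sets[names(ss)[states == "inactive"]]
      cs_a <- out$contact_sets[names(ss)[states == "active"]]
      fr <- compute_pair_frequencies(cs_i, cs_a, cls)
      sp <- filter_state_specific(fr, config$thresholds)
      cls_aln <- if ("gpcr_class" %in% names(aln)) {
        aln[aln$gpcr_class == cls, , drop = FALSE]
      } else aln
      sp <- conservation_filter(sp, cls_aln, config$thresholds$conservation_min)
      freqs[[cls]] <- fr
      specific[[cls]] <- sp
      dets[[cls]] <- classify_positions(sp, cls_aln)
    }
    out$pair_frequencies <- dplyr::bind_rows(freqs)
    out$state_specific <- dplyr::bind_rows(specific)
    out$determinants <- dplyr::bind_rows(dets)
    out$segment_network <- aggregate_segment_network(out$state_specific)
    write_table_with_header(
      dplyr::select(out$pair_frequencies, -"observed_aa_pairs"),
      file.path(config$output_dir, "pair_frequencies.tsv"), config)
    write_table_with_header(out$determinants,
                            file.path(config$output_dir, "determinants.tsv"),
                            config)
    jsonlite::write_json(
      list(edges = out$segment_network$edges,
           segments = out$segment_network$segments),
      file.path(config$output_dir, "segment_network.json"), digits = NA
    )
    # snakeplot-style payload: one record per determinant position
    jsonlite::write_json(
      out$determinants,
      file.path(config$output_dir, "snakeplot.json"), digits = NA
    )
  }

  if ("helixmove" %in% config$stages) {
    recs <- split(structures, vapply(structures, `[[`, "", "receptor"))
    reports <- list()
    for (rn in names(recs)) {
      states <- vapply(recs[[rn]], `[[`, "", "state")
      if (!any(states == "inactive") || !any(states == "active")) next
      reports[[rn]] <- helix_movement_report(
        recs[[rn]][[which(states == "inactive")[1]]],
        recs[[rn]][[which(states == "active")[1]]],
        spec = config$regions
      )
    }
    out$movements <- dplyr::bind_rows(reports)
    if (length(reports)) {
      out$consensus <- class_consensus_movements(out$movements)
      write_table_with_header(out$movements,
                              file.path(config$output_dir, "helix_movements.tsv"),
                              config)
      write_table_with_header(out$consensus,
                              file.path(config$output_dir,
                                        "movement_consensus.tsv"), config)
    }
  }

  if ("mutstats" %in% config$stages) {
    mt <- read_input(config$mutant_table, read_mutant_table)
    deltas <- delta_from_wt(mt)
    out$mutation_stats <- compare_mutant_groups(deltas)
    write_table_with_header(out$mutation_stats$comparison,
                            file.path(config$output_dir, "mutation_stats.tsv"),
                            config)
  }
  out
}
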