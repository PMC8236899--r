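#' @title End-to-end analysis pipeline
#' @description
#' Orchestrates the per-structure analyses (secondary structure, sheet
#' topology, bulge/cleft detectors, contacts, interfaces, peptide geometry,
#' knob insertion, disulfides) and the cross-structure comparisons
#' (superpositions, alignment identities and conservation labels) into one
#' deterministic report bundle. Timestamps are isolated in the provenance
#' section so that re-runs on identical inputs produce identical reports.
#' @name pipeline
NULL

DEFAULT_THRESHOLDS <- list(contact = 4.0, polar = 3.5, dsasa = 0.1,
                           knob = 0.6, sasa_points = 960)

#' Run the full analysis pipeline
#'
#' @param config a list or a YAML file path. Recognised fields:
#'   `structures` (list; each entry needs `id` plus either `path` (+
#'   optional `dialect`) and `numbering` (config list or YAML path), or
#'   pre-built `structure`/`map` objects), `alignment` (optional: `path` or
#'   `text`, `blocks`, `groups`), `thresholds` (contact/polar/dsasa/knob),
#'   `superpose_selector` (default `"pab"`), `seed` (default 1),
#'   `output_dir` (optional; reports are written there).
#' @return a `pmhc_report` list: `structures` (per-structure sections),
#'   `comparisons` (pairwise superpositions), `conservation` (identity
#'   matrices and column labels), `errors`, `provenance`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1) {
    if (!file.exists(config)) stop("no such pipeline config: ", config)
    config <- yaml::read_yaml(config)
  }
  thr <- utils::modifyList(DEFAULT_THRESHOLDS,
                           if (is.null(config$thresholds)) list() else
                             config$thresholds)
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  set.seed(seed)

  # validate referenced files before any computation
  for (entry in config$structures) {
    if (!is.null(entry$path) && !file.exists(entry$path))
      stop("structure file missing: ", entry$path)
    if (is.character(entry$numbering) && !file.exists(entry$numbering))
      stop("numbering config missing: ", entry$numbering)
  }
  if (!is.null(config$alignment$path) && !file.exists(config$alignment$path))
    stop("alignment file missing: ", config$alignment$path)

  errors <- list()
  loaded <- list()
  results <- list()
  for (entry in config$structures) {
    id <- entry$id
    sec <- tryCatch(
      analyse_structure(entry, thr),
      error = function(e) {
        errors[[id]] <<- conditionMessage(e)
        NULL
      })
    if (!is.null(sec)) {
      loaded[[id]] <- sec$input
      results[[id]] <- sec$report
    }
  }

  comparisons <- list()
  ids <- names(loaded)
  sel <- if (is.null(config$superpose_selector)) "pab" else
    config$superpose_selector
  if (length(ids) >= 2) {
    for (i in seq_len(length(ids) - 1)) for (j in (i + 1):length(ids)) {
      a <- loaded[[ids[i]]]; b <- loaded[[ids[j]]]
      key <- paste(ids[i], ids[j], sep = "_vs_")
      comparisons[[key]] <- tryCatch({
        sp <- superpose_by_domain(a$structure, a$map, b$structure, b$map,
                                  selector = sel)
        list(selector = sel, rmsd = sp$rmsd, n_fitted = sp$n_fitted)
      }, error = function(e) {
        errors[[key]] <<- conditionMessage(e)
        NULL
      })
    }
  }

  conservation <- NULL
  if (!is.null(config$alignment)) {
    conservation <- tryCatch({
      al <- config$alignment
      aln <- if (!is.null(al$object)) al$object else
        read_alignment(path = al$path, text = al$text,
                       block_config = al$blocks, groups = al$groups)
      idm <- lapply(names(aln$blocks), function(b)
        round(identity_matrix(aln, b)))
      names(idm) <- names(aln$blocks)
      labels <- if (!is.null(aln$groups))
        classify_alignment_conservation(aln) else NULL
      list(identity = idm, labels = labels)
    }, error = function(e) {
      errors[["alignment"]] <<- conditionMessage(e)
      NULL
    })
  }

  bundle <- structure(list(
    structures = results, comparisons = comparisons,
    conservation = conservation, errors = errors,
    provenance = list(
      package = as.character(utils::packageVersion("pmhcstruct")),
      r_version = R.version.string,
      seed = seed,
      config_hash = config_hash(config),
      generated_at = format(Sys.time(), tz = "UTC"))),
    class = "pmhc_report")
  if (!is.null(config$output_dir)) write_report_bundle(bundle,
                                                       config$output_dir)
  bundle
}

config_hash <- function(config) {
  config$output_dir <- NULL
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(jsonlite::toJSON(config, auto_unbox = TRUE, force = TRUE,
                              digits = NA), f)
  unname(tools::md5sum(f))
}

analyse_structure <- function(entry, thr) {
  if (!is.null(entry$structure)) {
    st <- entry$structure
    map <- entry$map
  } else {
    dialect <- if (is.null(entry$dialect)) "pdb" else entry$dialect
    st <- parse_structure(entry$path, dialect = dialect, id = entry$id,
                          is_path = TRUE)
    ncfg <- if (is.character(entry$numbering))
      read_numbering_config(entry$numbering) else entry$numbering
    map <- build_numbering_map(st, ncfg)
  }
  doms <- assign_domains(st, map)
  hb <- suppressWarnings(compute_backbone_hbonds(st))
  ss <- assign_secondary_structure(hb)
  topo <- withCallingHandlers(build_beta_topology(hb, ss, map),
                              warning = function(w) invokeRestart("muffleWarning"))
  bulges <- detect_beta_bulges(topo, st)
  clefts <- list(pa = detect_s2s3_cleft(topo, "pa"),
                 pb = detect_s2s3_cleft(topo, "pb"))
  contacts <- if (length(doms$peptide))
    contact_residues(st, doms$peptide, doms$pab, cutoff = thr$contact,
                     map = map) else NULL
  iface <- list()
  pairs <- list(c("ia", "pab"), c("ib", "pab"), c("ia", "ib"),
                c("peptide", "pab"))
  for (p in pairs) {
    if (!length(doms[[p[1]]]) || !length(doms[[p[2]]])) next
    key <- paste(p, collapse = "_")
    iface[[key]] <- interface_summary(
      st, doms[[p[1]]], doms[[p[2]]], dsasa_threshold = thr$dsasa,
      contact_cutoff = thr$contact, map = map, n_points = thr$sasa_points)
  }
  geometry <- if (sum(map$domain == "peptide") >= 2)
    peptide_geometry_report(st, map, ss = ss, sasa = TRUE) else NULL
  knob <- if (all(c("ia56", "ia60") %in% map$canon))
    knob_insertion(st, map, threshold = thr$knob,
                   n_points = thr$sasa_points) else NULL
  pep_exposed <- if (length(doms$peptide))
    peptide_exposed_surface(st, doms$peptide,
                            n_points = thr$sasa_points) else NULL
  report <- list(
    id = st$id,
    class_label = attr(map, "class_label"),
    n_residues = nrow(residue_table(st)),
    ss_table = ss[, c("reskey", "state", "state_name")],
    ss_string = paste(ss$state, collapse = ""),
    strands = topo$strands,
    bulges = bulges,
    clefts = lapply(clefts, function(x)
      x[c("domain_class", "last_pair", "cleft_present")]),
    peptide_pab_contacts = contacts,
    interfaces = lapply(iface, function(x) list(
      buried_area = x$buried_area,
      interface_residues_a = x$interface_residues_a,
      interface_residues_b = x$interface_residues_b,
      n_contacts = nrow(x$contacts))),
    peptide_geometry = if (!is.null(geometry)) list(
      register_distances = geometry$register_distances,
      bulge_height = geometry$bulge_height,
      orientation = as.list(geometry$orientation),
      terminal_exposure = as.list(geometry$terminal_exposure)) else NULL,
    knob = if (!is.null(knob)) knob[c("knob", "fractional_burial",
                                      "inserted")] else NULL,
    peptide_exposed_surface = pep_exposed,
    disulfides = detect_disulfides(st, map))
  list(input = list(structure = st, map = map), report = report)
}

#' Write a report bundle to disk
#'
#' JSON for the nested per-structure and cross-structure reports (identical
#' across re-runs on identical inputs), TSV for the per-residue secondary
#' structure tables, and a separate provenance file carrying the timestamp.
#'
#' @param bundle a `pmhc_report`.
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_report_bundle <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character()
  main <- bundle[c("structures", "comparisons", "conservation", "errors")]
  main$structures <- lapply(main$structures, function(s) {
    s$ss_table <- NULL        # written as TSV instead
    s
  })
  p <- file.path(dir, "report.json")
  jsonlite::write_json(main, p, auto_unbox = TRUE, digits = 6, null = "null",
                       pretty = TRUE, force = TRUE)
  paths <- c(paths, p)
  for (id in names(bundle$structures)) {
    tab <- bundle$structures[[id]]$ss_table
    p2 <- file.path(dir, paste0(id, "_ss.tsv"))
    utils::write.table(tab, p2, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <- c(paths, p2)
    ct <- bundle$structures[[id]]$peptide_pab_contacts
    if (!is.null(ct) && nrow(ct)) {
      p3 <- file.path(dir, paste0(id, "_contacts.tsv"))
      utils::write.table(ct, p3, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      paths <- c(paths, p3)
    }
  }
  pprov <- file.path(dir, "provenance.json")
  jsonlite::write_json(bundle$provenance, pprov, auto_unbox = TRUE,
                       pretty = TRUE)
  paths <- c(paths, pprov)
  invisible(paths)
}

#' @export
print.pmhc_report <- function(x, ...) {
  cat("pmhc_report:", length(x$structures), "structure(s),",
      length(x$comparisons), "comparison(s),",
      length(x$errors), "error(s)\n")
  for (id in names(x$structures)) {
    s <- x$structures[[id]]
    cat(" -", id, "(", s$class_label, "):", s$n_residues, "residues,",
        nrow(s$bulges), "bulge(s); cleft pa:",
        s$clefts$pa$cleft_present, "pb:", s$clefts$pb$cleft_present, "\n")
  }
  invisible(x)
}
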