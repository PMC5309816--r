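#' Pipeline run configuration
#'
#' A flat configuration driving [run_pipeline()]: which stages run, where
#' inputs come from, the filter thresholds and profile parameters, and one
#' global seed expanded into fixed per-stage substreams so individual stages
#' can be rerun reproducibly.
#'
#' When the `simulate` stage is enabled the remaining stages read from the
#' generated fixture bundle; otherwise explicit input paths must be supplied
#' via `paths` (`hits`, `groups`, `tree`, `aln`, `presence`, `proteome_dir`).
#'
#' @param out_dir Output directory.
#' @param stages Character vector of stages, in dependency order among
#'   `simulate`, `candidates`, `divergence`, `profile`, `dollo`, `pts1`,
#'   `report`.
#' @param seed Global integer seed.
#' @param sim Named list of [sim_config()] overrides.
#' @param thresholds A [filter_thresholds()].
#' @param window,order,n_nulls,gap_penalty,min_fraction Profile parameters.
#' @param profile_family Family id to profile (default: the first family
#'   whose truth class is `divergent`, else the first alignment).
#' @param paths Named list of explicit input paths.
#' @return A `run_config` list.
#' @export
run_config <- function(out_dir,
                       stages = c("simulate", "candidates", "divergence",
                                  "profile", "dollo", "pts1", "report"),
                       seed = 1, sim = list(),
                       thresholds = filter_thresholds(),
                       window = 41, order = 5, n_nulls = 1000000,
                       gap_penalty = 3, min_fraction = 0.7,
                       profile_family = NULL, paths = list()) {
  known <- c("simulate", "candidates", "divergence", "profile", "dollo",
             "pts1", "report")
  bad <- setdiff(stages, known)
  if (length(bad) > 0) stop("unknown stage(s): ", paste(bad, collapse = ", "),
                            call. = FALSE)
  structure(list(out_dir = out_dir, stages = stages, seed = as.integer(seed),
                 sim = sim, thresholds = thresholds, window = window,
                 order = order, n_nulls = n_nulls, gap_penalty = gap_penalty,
                 min_fraction = min_fraction, profile_family = profile_family,
                 paths = paths),
            class = "run_config")
}

#' Read a flat key=value pipeline configuration file
#'
#' Recognised keys: `out_dir`, `stages` (comma-separated), `seed`, `window`,
#' `order`, `n_nulls`, `gap_penalty`, `min_fraction`, `profile_family`,
#' `sim.<field>` ([sim_config()] overrides), and `path.<name>` input paths.
#'
#' @param path Configuration file.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  kv <- strsplit(lines, "=", fixed = TRUE)
  keys <- trimws(vapply(kv, `[[`, character(1), 1))
  vals <- trimws(vapply(kv, function(x) paste(x[-1], collapse = "="),
                        character(1)))
  get1 <- function(k, default = NULL) if (k %in% keys) vals[keys == k] else
    default
  num <- function(k, default) as.numeric(get1(k, default))
  sim_keys <- grep("^sim\\.", keys, value = TRUE)
  sim <- stats::setNames(
    lapply(sim_keys, function(k) {
      v <- vals[keys == k]
      suppressWarnings(if (!is.na(as.numeric(v))) as.numeric(v) else v)
    }), sub("^sim\\.", "", sim_keys))
  path_keys <- grep("^path\\.", keys, value = TRUE)
  paths <- stats::setNames(as.list(vals[match(path_keys, keys)]),
                           sub("^path\\.", "", path_keys))
  run_config(
    out_dir = get1("out_dir", stop("config must set out_dir", call. = FALSE)),
    stages = strsplit(get1("stages", paste(
      c("simulate", "candidates", "divergence", "profile", "dollo", "pts1",
        "report"), collapse = ",")), ",")[[1]],
    seed = num("seed", 1), sim = sim,
    window = num("window", 41), order = num("order", 5),
    n_nulls = num("n_nulls", 1e6), gap_penalty = num("gap_penalty", 3),
    min_fraction = num("min_fraction", 0.7),
    profile_family = get1("profile_family"), paths = paths)
}

stage_header <- function(config, stage, extra = "") {
  c(paste0("# divscan ", as.character(utils::packageVersion("divscan"))),
    paste0("# stage=", stage, " seed=", config$seed,
           if (nzchar(extra)) paste0(" ", extra) else ""))
}

#' Run the differential-conservation pipeline end to end
#'
#' Executes the enabled stages in dependency order, writing one TSV per
#' stage under `out_dir`, each with a comment header echoing the seed and
#' parameters. Outputs are a pure function of the configuration: rerunning
#' with the same configuration yields byte-identical files.
#'
#' @param config A `run_config` (or path to a key=value file).
#' @return Tibble manifest (`stage`, `path`), invisibly.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  stages <- config$stages
  bundle <- file.path(config$out_dir, "bundle")
  inp <- function(name, bundle_file) {
    p <- config$paths[[name]]
    if (is.null(p)) p <- file.path(bundle, bundle_file)
    p
  }
  # validate inputs for enabled stages before any computation
  need <- list(
    candidates = c(inp("hits", "hits.tsv"), inp("groups", "taxa.tsv")),
    divergence = inp("groups", "taxa.tsv"),
    profile = inp("groups", "taxa.tsv"),
    dollo = c(inp("tree", "species_tree.nwk"),
              inp("presence", "presence.tsv")),
    pts1 = inp("groups", "taxa.tsv"))
  if (!"simulate" %in% stages) {
    for (st in intersect(stages, names(need))) {
      missing <- need[[st]][!file.exists(need[[st]])]
      if (length(missing) > 0) {
        stop("stage '", st, "' is enabled but input(s) missing: ",
             paste(missing, collapse = ", "), call. = FALSE)
      }
    }
  }
  outputs <- list()
  emit <- function(stage, file) {
    outputs[[length(outputs) + 1]] <<- tibble::tibble(
      stage = stage, path = file)
  }

  if ("simulate" %in% stages) {
    cfg <- do.call(sim_config, utils::modifyList(
      list(seed = config$seed), config$sim))
    write_fixture_bundle(cfg, bundle)
    emit("simulate", file.path(bundle, "manifest.tsv"))
  }

  groups <- read_taxon_groups(inp("groups", "taxa.tsv"))

  if ("candidates" %in% stages) {
    hits <- read_hit_table(inp("hits", "hits.tsv"), dialect = "minimal",
                           ceiling = config$thresholds$presence_ceiling)
    cands <- classify_genes(hits, groups, config$thresholds)
    p <- file.path(config$out_dir, "candidates.tsv")
    write_report_tsv(cands, p, stage_header(config, "candidates"))
    emit("candidates", p)
    ps <- file.path(config$out_dir, "candidate_summary.tsv")
    write_report_tsv(summarize_candidates(cands), ps,
                     stage_header(config, "candidate_summary"))
    emit("candidates", ps)
  }

  if ("divergence" %in% stages) {
    tree_paths <- config$paths[["tree"]]
    if (is.null(tree_paths)) {
      td <- file.path(bundle, "gene_trees")
      tree_paths <- sort(list.files(td, pattern = "\\.nwk$",
                                    full.names = TRUE))
    }
    rows <- lapply(tree_paths, function(tp) {
      sc <- greyscale(divergence_scores(read_newick(tp), groups))
      sc$family_id <- sub("\\.nwk$", "", basename(tp))
      sc
    })
    p <- file.path(config$out_dir, "divergence.tsv")
    write_report_tsv(dplyr::bind_rows(rows), p,
                     stage_header(config, "divergence"))
    emit("divergence", p)
  }

  if ("profile" %in% stages) {
    aln_path <- config$paths[["aln"]]
    if (is.null(aln_path)) {
      fam <- config$profile_family
      if (is.null(fam)) {
        truth_path <- file.path(bundle, "truth.tsv")
        if (file.exists(truth_path)) {
          truth <- readr::read_tsv(truth_path, show_col_types = FALSE,
                                   progress = FALSE)
          fam <- truth$family_id[truth$class == "divergent"][1]
        }
      }
      if (is.null(fam) || is.na(fam)) {
        fam <- sub("\\.fasta$", "",
                   sort(list.files(file.path(bundle, "alignments")))[1])
      }
      aln_path <- file.path(bundle, "alignments", paste0(fam, ".fasta"))
    }
    aln <- read_alignment(aln_path, groups)
    prof <- build_profile(aln, window = config$window, order = config$order,
                          n_nulls = config$n_nulls,
                          gap_penalty = config$gap_penalty,
                          min_fraction = config$min_fraction,
                          seed = derive_seed(config$seed, 7001L))
    p <- file.path(config$out_dir, "profile.tsv")
    write_report_tsv(
      tidy(prof), p,
      stage_header(config, "profile",
                   sprintf("aln=%s window=%d order=%d n_nulls=%d",
                           basename(aln_path), config$window, config$order,
                           as.integer(config$n_nulls))))
    emit("profile", p)
  }

  if ("dollo" %in% stages) {
    tree <- read_newick(inp("tree", "species_tree.nwk"))
    presence <- read_presence_matrix(inp("presence", "presence.tsv"))
    glm <- gain_loss_map(tree, presence)
    p <- file.path(config$out_dir, "dollo_nodes.tsv")
    write_report_tsv(glm$nodes, p, stage_header(config, "dollo"))
    emit("dollo", p)
    pe <- file.path(config$out_dir, "dollo_events.tsv")
    write_report_tsv(glm$events, pe, stage_header(config, "dollo_events"))
    emit("dollo", pe)
  }

  if ("pts1" %in% stages) {
    pd <- config$paths[["proteome_dir"]]
    if (is.null(pd)) pd <- file.path(bundle, "proteomes")
    files <- sort(list.files(pd, pattern = "\\.fasta$", full.names = TRUE))
    res <- dplyr::bind_rows(lapply(files, function(f) {
      out <- pts1_percentage(read_fasta(f))
      out$species <- sub("\\.fasta$", "", basename(f))
      out[, c("species", "n_proteins", "n_matched", "percent")]
    }))
    p <- file.path(config$out_dir, "pts1.tsv")
    write_report_tsv(res, p, stage_header(config, "pts1"))
    emit("pts1", p)
  }

  if ("report" %in% stages) {
    p <- file.path(config$out_dir, "report.tsv")
    write_report_tsv(report_summary(config$out_dir, groups), p,
                     stage_header(config, "report"))
    emit("report", p)
  }

  invisible(dplyr::bind_rows(outputs))
}

#' One-row pipeline summary
#'
#' Collects the candidate counts and both/either fractions, plus mean PTS1
#' percentages by group when the PTS1 stage ran.
#'
#' @param out_dir Pipeline output directory containing stage TSVs.
#' @param groups Taxon-group tibble (for PTS1 group means).
#' @return One-row tibble.
#' @export
report_summary <- function(out_dir, groups = NULL) {
  cs_path <- file.path(out_dir, "candidate_summary.tsv")
  if (!file.exists(cs_path)) {
    stop("candidates stage output not found: ", cs_path, call. = FALSE)
  }
  out <- readr::read_tsv(cs_path, comment = "#", show_col_types = FALSE,
                         progress = FALSE)
  if (out$n_selected == 0) out$no_candidates_flag <- TRUE
  pts_path <- file.path(out_dir, "pts1.tsv")
  if (file.exists(pts_path) && !is.null(groups)) {
    pts <- readr::read_tsv(pts_path, comment = "#", show_col_types = FALSE,
                           progress = FALSE)
    for (g in intersect(unique(groups$group),
                        c("PEZ", "NEOLECTA", "SACCH", "TAPH_YEAST"))) {
      v <- pts$percent[pts$species %in% group_species(groups, g)]
      if (length(v) > 0) out[[paste0("pts1_pct_", tolower(g))]] <- mean(v)
    }
    yeast <- pts$percent[pts$species %in%
                           group_species(groups, c("SACCH", "TAPH_YEAST"))]
    pez <- pts$percent[pts$species %in% group_species(groups, "PEZ")]
    if (length(yeast) > 0 && length(pez) > 0 && mean(yeast) > 0) {
      out$pts1_ratio_pez_over_yeast <- mean(pez) / mean(yeast)
    }
  }
  out
}
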