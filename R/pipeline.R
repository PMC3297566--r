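#' Build and validate a pipeline run configuration
#'
#' The configuration is a nested key/value structure (a YAML file or an R
#' list) naming the inputs, contact specs, cutoffs and seeds of a run.
#' Validation is aggregated: every problem is reported at once.
#'
#' Recognised keys (all cutoffs in Angstrom, times as noted):
#' \describe{
#'   \item{output_dir}{Directory for all stage outputs.}
#'   \item{seed}{Integer seed used by every stochastic stage.}
#'   \item{trajectory}{Either `path`/`format`/`topology`/`dt_ps` for a file
#'     on disk, or `synthetic: true` with optional `n_frames`,
#'     `jitter_sigma` to use the built-in Markov generator.}
#'   \item{contacts}{List of contact entries (`name`, `kind`, `side_a`,
#'     `side_b`); default: the three monitored toy salt bridges.}
#'   \item{cutoffs}{`hbond_dist` (3.6), `hbond_angle_deg` (30),
#'     `ionic` (5), `leader_rmsd` (2), `burn_in_ns` (0),
#'     `rmsf_window_ns` (Inf).}
#'   \item{rmsf}{`chain` and optional `residues` for the reported
#'     selection.}
#'   \item{seqstats}{`alignment` (FASTA path), `loop_columns` (vector or
#'     path to a one-column file), `identity_cutoff` (0.5),
#'     `class_column`, `propensity_tables` (TSV path), `n_perm` (999),
#'     `position` (10).}
#' }
#'
#' @param config A YAML file path or a named list.
#' @return A validated `"run_config"` object.
#' @export
run_config <- function(config) {
  if (is.character(config) && length(config) == 1) {
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) {
    stop_validation("config must be a YAML file path or a named list")
  }
  defaults <- list(
    output_dir = "pdzmodes_out",
    seed = 1L,
    trajectory = list(synthetic = TRUE, n_frames = 20000L,
                      jitter_sigma = 0.15, dt_ps = 1),
    contacts = NULL,
    cutoffs = list(hbond_dist = 3.6, hbond_angle_deg = 30, ionic = 5,
                   leader_rmsd = 2, burn_in_ns = 0, rmsf_window_ns = Inf),
    rmsf = list(chain = "P"),
    seqstats = list(identity_cutoff = 0.5, n_perm = 999L, position = 10L)
  )
  if (!is.null(config$trajectory$path) &&
      is.null(config$trajectory$synthetic)) {
    config$trajectory$synthetic <- FALSE
  }
  cfg <- utils::modifyList(defaults, config)
  problems <- character(0)
  cut <- cfg$cutoffs
  for (k in c("hbond_dist", "hbond_angle_deg", "ionic", "leader_rmsd")) {
    if (!is.numeric(cut[[k]]) || cut[[k]] <= 0) {
      problems <- c(problems, sprintf("cutoff '%s' must be positive", k))
    }
  }
  if (cut$burn_in_ns < 0) problems <- c(problems, "burn_in_ns must be >= 0")
  tr <- cfg$trajectory
  if (!isTRUE(tr$synthetic)) {
    if (is.null(tr$path) || !file.exists(tr$path)) {
      problems <- c(problems,
                    sprintf("trajectory path '%s' does not exist",
                            tr$path %||% "<missing>"))
    }
    if (!is.null(tr$topology) && !file.exists(tr$topology)) {
      problems <- c(problems,
                    sprintf("topology path '%s' does not exist", tr$topology))
    }
  }
  ss <- cfg$seqstats
  for (k in c("alignment", "propensity_tables")) {
    if (!is.null(ss[[k]]) && !file.exists(ss[[k]])) {
      problems <- c(problems, sprintf("seqstats %s '%s' does not exist",
                                      k, ss[[k]]))
    }
  }
  if (length(problems) > 0) {
    stop_validation(paste0("invalid configuration:\n  - ",
                           paste(problems, collapse = "\n  - ")))
  }
  structure(cfg, class = "run_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_validation <- function(msg) {
  stop(structure(class = c("pdzmodes_validation_error", "error", "condition"),
                 list(message = msg, call = NULL)))
}

stop_dependency <- function(stage, missing) {
  stop(structure(class = c("pdzmodes_dependency_error", "error", "condition"),
                 list(message = sprintf(
                   "stage '%s' needs missing upstream output: %s",
                   stage, missing), call = NULL)))
}

#' Run the analysis pipeline
#'
#' Executes the requested stages in dependency order
#' (`contacts -> microstates -> network`; `rmsf` and `seqstats` independent;
#' `simulate` writes synthetic inputs) against a validated configuration.
#' Stage outputs are plain TSV/GraphML/JSON files under `output_dir`; a
#' `manifest.json` listing inputs, parameters and MD5 checksums of every
#' output makes a run reproducible and re-runs byte-checkable.
#'
#' @param config A [run_config()] (or anything it accepts).
#' @param stages Character subset of
#'   `c("simulate", "contacts", "microstates", "network", "rmsf",
#'   "seqstats")`.
#' @return The manifest (a list), invisibly.
#' @export
run_pipeline <- function(config,
                         stages = c("contacts", "microstates", "network")) {
  cfg <- if (inherits(config, "run_config")) config else run_config(config)
  all_stages <- c("simulate", "contacts", "microstates", "network",
                  "rmsf", "seqstats")
  bad <- setdiff(stages, all_stages)
  if (length(bad) > 0) stop_validation(paste("unknown stage(s):",
                                             paste(bad, collapse = ", ")))
  stages <- all_stages[all_stages %in% stages]
  out <- cfg$output_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(tool = "pdzmodes",
                   version = as.character(utils::packageVersion("pdzmodes")),
                   seed = cfg$seed, parameters = cfg$cutoffs,
                   stages = list(), outputs = list())
  traj_cache <- NULL

  load_traj <- function() {
    if (!is.null(traj_cache)) return(traj_cache)
    tr <- cfg$trajectory
    t <- if (isTRUE(tr$synthetic)) {
      spec <- traj_generator_spec(
        n_frames = tr$n_frames %||% 20000L,
        jitter_sigma = tr$jitter_sigma %||% 0.15,
        dt_ps = tr$dt_ps %||% 1, seed = cfg$seed)
      gen_markov_trajectory(spec)$trajectory
    } else {
      read_trajectory(tr$path, tr$format %||% "pdb_multimodel",
                      topology_path = tr$topology, dt_ps = tr$dt_ps %||% 1)
    }
    if (cfg$cutoffs$burn_in_ns > 0) {
      t <- discard_equilibration(t, cfg$cutoffs$burn_in_ns)
    }
    traj_cache <<- t
    t
  }
  contact_spec_list <- function() {
    if (is.null(cfg$contacts)) return(toy_contact_specs())
    purrr::map(cfg$contacts, function(cc) {
      contact_spec(cc$name, cc$kind, cc$side_a, cc$side_b,
                   angle_cutoff_deg = cfg$cutoffs$hbond_angle_deg,
                   dist_cutoff = cfg$cutoffs$hbond_dist,
                   ionic_cutoff = cfg$cutoffs$ionic)
    })
  }

  for (stage in stages) {
    files <- switch(
      stage,
      simulate = {
        traj <- load_traj()
        p1 <- file.path(out, "synthetic_trajectory.pdb")
        write_trajectory(traj, p1)
        p2 <- file.path(out, "synthetic_topology.tsv")
        write_topology(traj, p2)
        msa <- gen_msa(msa_generator_spec(seed = cfg$seed))
        p3 <- file.path(out, "synthetic_alignment.fasta")
        write_alignment(msa$sequences, p3)
        truth <- list(loop_columns = msa$loop_columns,
                      groups = msa$groups)
        p4 <- file.path(out, "synthetic_ground_truth.json")
        jsonlite::write_json(truth, p4, auto_unbox = TRUE, pretty = TRUE)
        c(p1, p2, p3, p4)
      },
      contacts = {
        traj <- load_traj()
        recs <- contact_timeseries(traj, contact_spec_list())
        write_contacts(recs, file.path(out, "contacts"))
      },
      microstates = {
        summary_file <- file.path(out, "contacts", "contacts_summary.tsv")
        if (!file.exists(summary_file)) {
          stop_dependency("microstates", "contacts/contacts_summary.tsv")
        }
        traj <- load_traj()
        recs <- read_contact_records(file.path(out, "contacts"))
        sel <- select_backbone(traj, chain = cfg$rmsf$chain %||% "P")
        cl <- leader_cluster(traj, sel, cutoff = cfg$cutoffs$leader_rmsd)
        codes <- encode_microstates(recs, cl)
        p <- file.path(out, "microstates.tsv")
        readr::write_tsv(tibble::tibble(frame_time = traj$frame_times,
                                        code = codes), p)
        p
      },
      network = {
        ms_file <- file.path(out, "microstates.tsv")
        if (!file.exists(ms_file)) {
          stop_dependency("network", "microstates.tsv")
        }
        codes <- readr::read_tsv(ms_file, show_col_types = FALSE,
                                 col_types = readr::cols(
                                   code = readr::col_character()))$code
        csn <- build_csn(codes)
        basins <- gradient_cluster(csn)
        coarse <- coarse_grain(csn, basins)
        f1 <- write_network(csn, file.path(out, "csn"))
        f2 <- write_network(coarse, file.path(out, "coarse"))
        f3 <- write_basins(basins, file.path(out, "basins.tsv"))
        c(f1, f2, f3)
      },
      rmsf = {
        traj <- load_traj()
        sel <- select_backbone(traj, chain = cfg$rmsf$chain %||% "P",
                               residues = cfg$rmsf$residues)
        prof <- compute_rmsf(traj, sel,
                             window_ns = cfg$cutoffs$rmsf_window_ns)
        p <- file.path(out, "rmsf.tsv")
        write_rmsf(prof, p)
        p
      },
      seqstats = {
        ss <- cfg$seqstats
        if (is.null(ss$alignment)) {
          stop_dependency("seqstats", "an alignment (seqstats$alignment)")
        }
        seqs <- read_alignment(ss$alignment)
        loops <- ss$loop_columns
        if (is.character(loops) && length(loops) == 1 &&
            file.exists(loops)) {
          loops <- as.integer(readLines(loops))
        }
        wmsa <- group_paralogs(seqs,
                               identity_cutoff = ss$identity_cutoff %||% 0.5)
        enr <- loop_enrichment(wmsa, loops)
        p1 <- file.path(out, "enrichment.tsv")
        readr::write_tsv(tidy(enr), p1)
        p2 <- file.path(out, "enrichment.json")
        jsonlite::write_json(as.list(tidy(enr)), p2, auto_unbox = TRUE,
                             digits = NA, pretty = TRUE)
        files <- c(p1, p2)
        if (!is.null(ss$propensity_tables) && !is.null(ss$class_column)) {
          tabs <- read_propensity_tables(ss$propensity_tables)
          prof <- propensity_profile(tabs, wmsa, ss$class_column)
          p3 <- file.path(out, "propensity_profile.tsv")
          readr::write_tsv(tibble::as_tibble(prof), p3)
          files <- c(files, p3)
        }
        files
      })
    manifest$stages[[stage]] <- list(outputs = basename(files))
    for (f in files) {
      manifest$outputs[[sub(paste0("^", out, "/?"), "", f)]] <-
        unname(tools::md5sum(f))
    }
  }
  manifest_path <- file.path(out, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(manifest)
}

# Read back per-contact TSVs written by write_contacts(), restoring a
# contact_records tibble (kinds and order from the summary table).
read_contact_records <- function(dir) {
  summary <- readr::read_tsv(file.path(dir, "contacts_summary.tsv"),
                             show_col_types = FALSE)
  rows <- purrr::pmap(summary, function(name, kind, occupancy) {
    safe <- gsub("[^A-Za-z0-9_.-]", "_", name)
    tab <- readr::read_tsv(file.path(dir, paste0("contact_", safe, ".tsv")),
                           show_col_types = FALSE)
    tibble::tibble(name = name, kind = kind,
                   occupancy = mean(tab$formed == 1),
                   formed = list(tab$formed == 1))
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("contact_records", class(out))
  out
}
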