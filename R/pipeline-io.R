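# Shared readers/writers (CSV tables, epoch container + JSON sidecar),
# input validation, run configuration, and the end-to-end orchestration
# running simulate -> analyze -> report from a single config.

# Tabular IO ----------------------------------------------------------------

#' Write/read a behavioral session table
#'
#' CSV with columns `participant_id`, `trial_index`, `morph_pct`,
#' `choice`, `rt_s`, `confidence`, `confidence_rt_s`, `group_label`.
#'
#' @param session Behavioral session data.frame.
#' @param path Output CSV path.
#' @return `write_behavior_csv` returns `path` invisibly;
#'   `read_behavior_csv` returns the session data.frame.
#' @export
write_behavior_csv <- function(session, path) {
  utils::write.csv(session, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_behavior_csv
#' @export
read_behavior_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Write/read a spike dataset
#'
#' Two CSVs: `<base>.csv` with one row per spike (`neuron_id`, `region`,
#' `trial_id`, `spike_time_s`, `ambiguity_level`) and `<base>_trials.csv`
#' with one row per neuron x trial, so zero-spike trials survive the
#' round trip. The trial duration is stored in the trials file header
#' column `trial_duration_s`.
#'
#' @param dataset A [spike_dataset()].
#' @param base Path prefix (without extension).
#' @return `write_spike_csv` returns the two paths invisibly;
#'   `read_spike_csv` returns a [spike_dataset()].
#' @export
write_spike_csv <- function(dataset, base) {
  p1 <- paste0(base, ".csv")
  p2 <- paste0(base, "_trials.csv")
  utils::write.csv(dataset$spikes, p1, row.names = FALSE)
  tr <- dataset$trials
  tr$trial_duration_s <- dataset$trial_duration
  utils::write.csv(tr, p2, row.names = FALSE)
  invisible(c(spikes = p1, trials = p2))
}

#' @rdname write_spike_csv
#' @export
read_spike_csv <- function(base) {
  spikes <- utils::read.csv(paste0(base, ".csv"), stringsAsFactors = FALSE)
  tr <- utils::read.csv(paste0(base, "_trials.csv"),
                        stringsAsFactors = FALSE)
  dur <- tr$trial_duration_s[1]
  tr$trial_duration_s <- NULL
  spike_dataset(spikes, tr, dur)
}

#' Write/read EEG epochs as a wide CSV plus JSON sidecar
#'
#' The array container is a plain CSV with columns `trial`, `channel`,
#' then one column per sample (`s1..sN`), one row per trial x channel.
#' The JSON sidecar (`<base>.json`) records `fs`, `t0`, `channel_names`,
#' `condition` per trial, and `participant_id`.
#'
#' @param epochs An [eeg_epochs()] object.
#' @param base Path prefix (without extension).
#' @return `write_eeg_epochs` returns the two paths invisibly;
#'   `read_eeg_epochs` returns an [eeg_epochs()].
#' @export
write_eeg_epochs <- function(epochs, base) {
  d <- epochs$data
  nc <- dim(d)[1]; ns <- dim(d)[2]; nt <- dim(d)[3]
  flat <- matrix(0, nc * nt, ns)
  meta <- data.frame(trial = rep(seq_len(nt), each = nc),
                     channel = rep(epochs$channel_names, nt))
  for (tr in seq_len(nt)) {
    flat[(tr - 1) * nc + seq_len(nc), ] <- d[, , tr]
  }
  colnames(flat) <- sprintf("s%d", seq_len(ns))
  p1 <- paste0(base, ".csv")
  p2 <- paste0(base, ".json")
  utils::write.csv(cbind(meta, as.data.frame(flat)), p1,
                   row.names = FALSE)
  jsonlite::write_json(list(fs = epochs$fs, t0 = epochs$t0,
                            channel_names = epochs$channel_names,
                            condition = epochs$condition,
                            participant_id = epochs$participant_id),
                       p2, auto_unbox = TRUE, digits = NA)
  invisible(c(data = p1, sidecar = p2))
}

#' @rdname write_eeg_epochs
#' @export
read_eeg_epochs <- function(base) {
  p2 <- paste0(base, ".json")
  if (!file.exists(p2)) stop_invalid("missing sidecar: ", p2)
  side <- tryCatch(jsonlite::read_json(p2, simplifyVector = TRUE),
                   error = function(e) {
                     stop_invalid("corrupt epoch sidecar: ", p2)
                   })
  need <- c("fs", "t0", "channel_names", "condition")
  if (!all(need %in% names(side))) {
    stop_invalid("corrupt epoch sidecar (missing fields): ", p2)
  }
  tab <- utils::read.csv(paste0(base, ".csv"), stringsAsFactors = FALSE,
                         check.names = FALSE)
  nc <- length(side$channel_names)
  nt <- length(side$condition)
  ns <- ncol(tab) - 2
  d <- array(0, dim = c(nc, ns, nt))
  vals <- as.matrix(tab[, -(1:2), drop = FALSE])
  for (tr in seq_len(nt)) {
    d[, , tr] <- vals[(tr - 1) * nc + seq_len(nc), , drop = FALSE]
  }
  eeg_epochs(d, fs = side$fs, t0 = side$t0,
             channel_names = side$channel_names,
             condition = side$condition,
             participant_id = side$participant_id %||% "unknown")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write/read source time series as CSV
#'
#' Wide format: one column per source plus a `trial` column; trials are
#' concatenated along rows. Sampling rate is stored in a JSON sidecar.
#'
#' @param series A [source_series()].
#' @param base Path prefix.
#' @return Paths invisibly / a [source_series()].
#' @export
write_source_csv <- function(series, base) {
  d <- series$data
  n <- dim(d)[1]; ns <- dim(d)[2]; nt <- dim(d)[3]
  tab <- do.call(rbind, lapply(seq_len(nt), function(tr) {
    cbind(data.frame(trial = tr), as.data.frame(t(d[, , tr])))
  }))
  names(tab) <- c("trial", series$source_names)
  p1 <- paste0(base, ".csv"); p2 <- paste0(base, ".json")
  utils::write.csv(tab, p1, row.names = FALSE)
  jsonlite::write_json(list(fs = series$fs,
                            source_names = series$source_names),
                       p2, auto_unbox = TRUE, digits = NA)
  invisible(c(data = p1, sidecar = p2))
}

#' @rdname write_source_csv
#' @export
read_source_csv <- function(base) {
  side <- jsonlite::read_json(paste0(base, ".json"),
                              simplifyVector = TRUE)
  tab <- utils::read.csv(paste0(base, ".csv"), stringsAsFactors = FALSE)
  trials <- unique(tab$trial)
  src <- setdiff(names(tab), "trial")
  ns <- sum(tab$trial == trials[1])
  d <- array(0, dim = c(length(src), ns, length(trials)))
  for (i in seq_along(trials)) {
    d[, , i] <- t(as.matrix(tab[tab$trial == trials[i], src]))
  }
  source_series(d, fs = side$fs, source_names = src)
}

# Validation ----------------------------------------------------------------

#' Validate pipeline input files
#'
#' Schema and unit sanity checks for the tabular inputs. Reports problems
#' as character strings; never mutates inputs. Heuristic: RT columns with
#' a median above 10 are flagged as likely milliseconds (all package
#' analyses expect seconds).
#'
#' @param behavior_csv,spike_base,epochs_base Optional paths (spike and
#'   epoch arguments are path prefixes as used by the writers).
#' @return Character vector of problems (empty when all checks pass).
#' @export
validate_inputs <- function(behavior_csv = NULL, spike_base = NULL,
                            epochs_base = NULL) {
  problems <- character(0)
  note <- function(...) problems <<- c(problems, paste0(...))
  if (!is.null(behavior_csv)) {
    if (!file.exists(behavior_csv)) {
      note("behavior: file not found: ", behavior_csv)
    } else {
      b <- utils::read.csv(behavior_csv, stringsAsFactors = FALSE)
      need <- c("participant_id", "morph_pct", "choice", "rt_s")
      miss <- setdiff(need, names(b))
      if (length(miss)) {
        note("behavior: missing column(s): ", paste(miss, collapse = ", "))
      } else {
        off <- setdiff(unique(b$morph_pct), morph_grid())
        if (length(off)) {
          note("behavior: morph_pct off the task grid: ",
               paste(off, collapse = ", "))
        }
        if (any(!b$choice %in% c("fear", "happy"))) {
          note("behavior: choice values outside {fear, happy}")
        }
        rt <- b$rt_s[is.finite(b$rt_s)]
        if (length(rt) && stats::median(rt) > 10) {
          note("behavior: rt_s median > 10; values look like milliseconds,",
               " expected seconds")
        }
        if (any(stats::na.omit(b$rt_s) <= 0)) {
          note("behavior: non-positive rt_s values")
        }
        if ("confidence" %in% names(b) &&
            any(!stats::na.omit(b$confidence) %in% 1:3)) {
          note("behavior: confidence outside 1-3")
        }
      }
    }
  }
  if (!is.null(spike_base)) {
    p1 <- paste0(spike_base, ".csv"); p2 <- paste0(spike_base,
                                                   "_trials.csv")
    if (!file.exists(p1) || !file.exists(p2)) {
      note("spikes: missing ", p1, " and/or ", p2)
    } else {
      s <- utils::read.csv(p1, stringsAsFactors = FALSE)
      need <- c("neuron_id", "region", "trial_id", "spike_time_s",
                "ambiguity_level")
      miss <- setdiff(need, names(s))
      if (length(miss)) {
        note("spikes: missing column(s): ", paste(miss, collapse = ", "))
      } else if (any(!s$ambiguity_level %in% ambiguity_levels())) {
        note("spikes: unknown ambiguity_level values")
      }
    }
  }
  if (!is.null(epochs_base)) {
    p2 <- paste0(epochs_base, ".json")
    if (!file.exists(p2)) {
      note("epochs: missing sidecar ", p2)
    } else {
      side <- tryCatch(jsonlite::read_json(p2, simplifyVector = TRUE),
                       error = function(e) NULL)
      if (is.null(side) ||
          !all(c("fs", "t0", "channel_names", "condition") %in%
               names(side))) {
        note("epochs: corrupt or incomplete sidecar ", p2)
      }
    }
  }
  problems
}

# Orchestration --------------------------------------------------------------

#' Build a pipeline run configuration
#'
#' One global `seed` expands into per-stage seeds as
#' `seed + 1000 * stage_index` with stage indices behavior = 1,
#' spikes = 2, eeg = 3, mvar = 4, prediction = 5, so each stage is
#' reproducible in isolation.
#'
#' @param seed Global integer seed.
#' @param out_dir Output directory for stage files.
#' @param stages Character vector of enabled stages, a subset of
#'   `c("behavior", "spikes", "eeg", "mvar", "prediction")`.
#' @param params Optional named list of per-stage parameter overrides
#'   (each entry a list passed to the stage's truth constructor).
#' @return Object of class `run_config`.
#' @export
run_config <- function(seed = 1, out_dir = tempfile("ambiguitynet_run_"),
                       stages = c("behavior", "spikes", "eeg", "mvar",
                                  "prediction"),
                       params = list()) {
  all_stages <- c("behavior", "spikes", "eeg", "mvar", "prediction")
  bad <- setdiff(stages, all_stages)
  if (length(bad)) stop_invalid("unknown stage(s): ",
                                paste(bad, collapse = ", "))
  structure(list(seed = check_count(seed, "seed", min = 0),
                 out_dir = out_dir, stages = stages, params = params),
            class = "run_config")
}

config_to_json <- function(config) {
  jsonlite::toJSON(list(seed = config$seed, stages = config$stages,
                        params = config$params),
                   auto_unbox = TRUE, digits = NA)
}

#' Run the full simulate-analyze-report pipeline
#'
#' Executes the enabled stages in dependency order (simulation feeding
#' each analysis), writes stage outputs under `config$out_dir`, and
#' returns a run report. Identical config + seed give identical payloads
#' (timestamps aside). A stage failure aborts with the stage name.
#'
#' @param config A [run_config()].
#' @return Object of class `run_report`: list with `config_hash`,
#'   `outputs` (named file paths, all existing), `summaries` (per-stage
#'   key numbers), `version`, `wall_time_s`.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "run_config")) {
    stop_invalid("config must be a run_config")
  }
  t_start <- Sys.time()
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  outputs <- character(0)
  summaries <- list()
  hash <- config_hash(as.character(config_to_json(config)))
  run_stage <- function(name, body) {
    tryCatch(body(), error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  pars <- function(stage, defaults) {
    utils::modifyList(defaults, config$params[[stage]] %||% list())
  }
  delta_rt_groups <- NULL

  if ("behavior" %in% config$stages) {
    run_stage("behavior", function() {
      sd1 <- stage_seed(config$seed, 1)
      tr_ctrl <- do.call(behavior_truth,
                         pars("behavior", list(seed = sd1)))
      tr_pat <- do.call(behavior_truth,
                        pars("behavior_patient",
                             list(seed = sd1 + 1,
                                  rt_ambiguity_gain = 0.30)))
      n_per_group <- 12
      sess <- list()
      for (i in seq_len(n_per_group)) {
        tc <- tr_ctrl; tc$seed <- sd1 + 10L * i
        tp <- tr_pat; tp$seed <- sd1 + 10L * i + 5L
        sess[[i]] <- gen_behavior(tc, sprintf("ctrl%02d", i), "control")
        sess[[n_per_group + i]] <-
          gen_behavior(tp, sprintf("pat%02d", i), "patient")
      }
      all_b <- do.call(rbind, sess)
      path <- file.path(config$out_dir, "behavior.csv")
      write_behavior_csv(all_b, path)
      outputs["behavior"] <<- path
      fits <- lapply(split(all_b, all_b$participant_id), fit_psychometric)
      dr <- vapply(split(all_b, all_b$participant_id),
                   function(s) ambiguity_sensitivity(s)$delta_rt,
                   numeric(1))
      grp <- vapply(split(all_b, all_b$participant_id),
                    function(s) s$group_label[1], character(1))
      delta_rt_groups <<- split(unname(dr), grp)
      fit_tab <- data.frame(
        participant_id = names(fits),
        p_inf = vapply(fits, `[[`, numeric(1), "p_inf"),
        x_half = vapply(fits, `[[`, numeric(1), "x_half"),
        alpha_slope = vapply(fits, `[[`, numeric(1), "alpha_slope"),
        converged = vapply(fits, `[[`, logical(1), "converged"),
        delta_rt_s = unname(dr), group_label = unname(grp))
      fpath <- file.path(config$out_dir, "psychometric_fits.csv")
      utils::write.csv(fit_tab, fpath, row.names = FALSE)
      outputs["psychometric_fits"] <<- fpath
      summaries$behavior <<- list(
        n_participants = length(fits),
        median_x_half = stats::median(fit_tab$x_half, na.rm = TRUE),
        mean_delta_rt_control = mean(dr[grp == "control"]))
    })
  }

  if ("spikes" %in% config$stages) {
    run_stage("spikes", function() {
      sd2 <- stage_seed(config$seed, 2)
      tr <- do.call(spike_truth,
                    pars("spikes", list(n_neurons = 20,
                                        modulation_per_level = -2,
                                        seed = sd2)))
      ds <- filter_units(gen_spikes(tr))
      base <- file.path(config$out_dir, "spikes")
      write_spike_csv(ds, base)
      outputs["spikes"] <<- paste0(base, ".csv")
      sel <- select_ambiguity_neurons(ds)
      spath <- file.path(config$out_dir, "neuron_selection.csv")
      utils::write.csv(sel, spath, row.names = FALSE)
      outputs["neuron_selection"] <<- spath
      summaries$spikes <<- list(
        n_neurons = nrow(sel), n_selected = sum(sel$selected),
        binomial_p = population_binomial(sum(sel$selected), nrow(sel)))
    })
  }

  if ("eeg" %in% config$stages) {
    run_stage("eeg", function() {
      sd3 <- stage_seed(config$seed, 3)
      targets <- data.frame(chan_a = "Pz", chan_b = "Cz",
                            band = c("theta", "alpha"),
                            condition = NA_character_,
                            coherence = 0.5)
      tr <- do.call(eeg_truth,
                    pars("eeg", list(coherence_targets = targets,
                                     cfc_gain = c(anchor = 0.2,
                                                  intermediate = 0.4,
                                                  high = 0.6),
                                     seed = sd3)))
      ep <- gen_eeg_epochs(tr)
      base <- file.path(config$out_dir, "epochs")
      write_eeg_epochs(ep, base)
      outputs["epochs"] <<- paste0(base, ".csv")
      coh <- lapply(ambiguity_levels(), function(cd) {
        coherence_map(ep, condition = cd)$band_mean
      })
      coh_tab <- data.frame(channel = ep$channel_names,
                            anchor = coh[[1]], intermediate = coh[[2]],
                            high = coh[[3]])
      cpath <- file.path(config$out_dir, "coherence_band_means.csv")
      utils::write.csv(coh_tab, cpath, row.names = FALSE)
      outputs["coherence"] <<- cpath
      cfc <- lapply(ambiguity_levels(), function(cd) {
        amplitude_cfc(ep, condition = cd, seed = sd3)$modulation_index
      })
      summaries$eeg <<- list(
        pz_cz_coherence = unname(coh_tab[coh_tab$channel == "Cz",
                                         "anchor"]),
        cfc_by_condition = stats::setNames(unlist(cfc),
                                           ambiguity_levels()))
    })
  }

  if ("mvar" %in% config$stages) {
    run_stage("mvar", function() {
      sd4 <- stage_seed(config$seed, 4)
      A1 <- matrix(c(0.5, 0.4, 0, 0.5), 2, 2, byrow = FALSE)
      tr <- do.call(mvar_truth,
                    pars("mvar", list(coeff_matrices = list(A1),
                                      n_samples = 200, n_trials = 30,
                                      seed = sd4)))
      ser <- gen_mvar_series(tr)
      base <- file.path(config$out_dir, "sources")
      write_source_csv(ser, base)
      outputs["sources"] <<- paste0(base, ".csv")
      model <- fit_mvar(ser, order = tr$order)
      g <- dtf(model)
      sig <- dtf_significance(ser, order = tr$order, n_perm = 200,
                              seed = sd4)
      jpath <- file.path(config$out_dir, "dtf_summary.json")
      jsonlite::write_json(
        list(band_mean = dtf_band_mean(g),
             p_values = sig$p_values, n_perm = sig$n_perm,
             seed = sig$seed, order = model$order),
        jpath, auto_unbox = TRUE, digits = NA, na = "null")
      outputs["dtf_summary"] <<- jpath
      summaries$mvar <<- list(order = model$order,
                              stable = model$stable,
                              flow_1_to_2 = dtf_band_mean(g)[2, 1],
                              p_1_to_2 = sig$p_values[2, 1])
    })
  }

  if ("prediction" %in% config$stages) {
    run_stage("prediction", function() {
      if (is.null(delta_rt_groups)) {
        stop("prediction stage requires the behavior stage")
      }
      gp <- compare_groups_prediction(delta_rt_groups,
                                      control_label = "control")
      ppath <- file.path(config$out_dir, "prediction_comparisons.csv")
      utils::write.csv(gp$comparisons, ppath, row.names = FALSE)
      outputs["prediction"] <<- ppath
      summaries$prediction <<- list(
        mean_y_control = mean(gp$predicted$control),
        comparisons = gp$comparisons)
    })
  }

  missing <- outputs[!file.exists(outputs)]
  if (length(missing)) {
    stop_invalid("run report references missing files: ",
                 paste(missing, collapse = ", "))
  }
  structure(list(config_hash = hash, outputs = outputs,
                 summaries = summaries,
                 version = as.character(utils::packageVersion("ambiguitynet")),
                 wall_time_s = as.numeric(difftime(Sys.time(), t_start,
                                                   units = "secs"))),
            class = "run_report")
}
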