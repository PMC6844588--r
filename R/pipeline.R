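#' Assemble a pipeline run configuration
#'
#' @param outdir output directory (created if absent).
#' @param input path to a long-format panel CSV, or `NULL` to run the
#'   `simulate` stage instead.
#' @param stages stages to execute, any of `simulate`, `impute`,
#'   `describe`, `fit`, `lifetable`, `cox`; executed in dependency order
#'   (simulate, impute, describe, fit, lifetable, cox).
#' @param seed integer seed recorded in every artifact.
#' @param n subjects for the `simulate` stage.
#' @param structure transition structure (`"full"` or `"no-jump"`).
#' @param age_form `"loglinear"` or `"bands"`.
#' @param bootstrap_B bootstrap resamples for life-table CIs (default 499).
#' @param lifetable_ci compute bootstrap CIs in the lifetable stage (off by
#'   default; full refits are expensive).
#' @param index_ages,max_age,step,window life-table settings.
#' @param m,k multiple-imputation settings for the `impute` stage.
#' @return A `run_config` list.
#' @export
run_config <- function(outdir, input = NULL,
                       stages = c("simulate", "describe", "fit",
                                  "lifetable", "cox"),
                       seed = 1L, n = 2000L,
                       structure = c("full", "no-jump"),
                       age_form = c("loglinear", "bands"),
                       bootstrap_B = 499L, lifetable_ci = FALSE,
                       index_ages = c(65, 75, 85, 95), max_age = 115,
                       step = 0.25, window = 2.5, m = 5L, k = 5L) {
  structure_choice <- match.arg(structure)
  age_form <- match.arg(age_form)
  known <- c("simulate", "impute", "describe", "fit", "lifetable", "cox")
  if (!all(stages %in% known)) {
    stop("unknown stage(s): ", paste(setdiff(stages, known), collapse = ", "))
  }
  structure(list(outdir = outdir, input = input,
                 stages = known[known %in% stages], seed = as.integer(seed),
                 n = as.integer(n), structure = structure_choice,
                 age_form = age_form, bootstrap_B = as.integer(bootstrap_B),
                 lifetable_ci = lifetable_ci, index_ages = index_ages,
                 max_age = max_age, step = step, window = window,
                 m = as.integer(m), k = as.integer(k)),
            class = "run_config")
}

#' Execute the analysis pipeline
#'
#' Runs the requested stages in dependency order on a panel cohort (read
#' from `config$input` or generated by the `simulate` stage), writing each
#' stage's artifact to `config$outdir` and a `manifest.json` listing every
#' output with an md5 content hash, the seed, package and R versions, stage
#' timings and failures. A stage failure is recorded in the manifest and
#' reflected in a nonzero status without aborting later independent stages.
#'
#' @param config a [run_config()].
#' @return Invisibly, a list with `status` (0 = all stages succeeded) and
#'   the `manifest`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(seed = config$seed,
                   r_version = as.character(getRversion()),
                   package_version =
                     as.character(utils::packageVersion("eldertrans")),
                   stages = list(), files = list())
  status <- 0L
  cohort <- NULL
  imputations <- NULL
  fit <- NULL
  art <- function(name) file.path(config$outdir, name)
  run_stage <- function(stage, fun) {
    t0 <- Sys.time()
    res <- tryCatch(list(ok = TRUE, value = fun()),
                    error = function(e) list(ok = FALSE, error = conditionMessage(e)))
    elapsed <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
    manifest$stages[[stage]] <<- list(
      ok = res$ok, seconds = round(elapsed, 3),
      error = if (!res$ok) res$error)
    if (!res$ok) {
      status <<- 1L
      message("stage '", stage, "' failed: ", res$error)
      return(NULL)
    }
    res$value
  }

  if (!is.null(config$input)) {
    cohort <- run_stage("read", function() read_panel(config$input))
  }
  for (stage in config$stages) {
    if (stage == "simulate") {
      sim <- run_stage("simulate", function() {
        scen <- simulation_scenario(n = config$n, seed = config$seed)
        out <- generate_cohort(scen, truth_sim_n = 0L)
        write_panel(out$cohort, art("cohort.csv"))
        write_truth_json(out$truth, art("truth.json"))
        out
      })
      if (!is.null(sim) && is.null(cohort)) cohort <- sim$cohort
    } else if (is.null(cohort)) {
      manifest$stages[[stage]] <- list(ok = FALSE, seconds = 0,
                                       error = "no cohort available")
      status <- 1L
    } else if (stage == "impute") {
      imputations <- run_stage("impute", function() {
        imp <- impute_pmm(cohort, m = config$m, k = config$k,
                          seed = config$seed)
        write_imputed_csv(imp, art("imputed.csv"))
        imp
      })
    } else if (stage == "describe") {
      run_stage("describe", function() {
        tab <- descriptive_table(cohort)
        utils::write.csv(tab, art("descriptive.csv"), row.names = FALSE,
                         na = "")
        tab
      })
    } else if (stage == "fit") {
      fit <- run_stage("fit", function() {
        model <- intensity_model(config$structure,
                                 covariates = c("female", "rural"),
                                 age_form = config$age_form)
        f <- fit_mle(cohort, model)
        write_fit_json(f, art("fit.json"), seed = config$seed)
        curves <- do.call(rbind, lapply(c("male", "female"), function(sx) {
          do.call(rbind, lapply(c("urban", "rural"), function(rg) {
            cv <- annual_probability_curves(
              f, stratum_profile(f$model, sx, rg), ages = 65:95)
            cbind(sex = sx, region = rg, cv)
          }))
        }))
        utils::write.csv(curves, art("annual_probabilities.csv"),
                         row.names = FALSE)
        f
      })
    } else if (stage == "lifetable") {
      if (is.null(fit)) {
        manifest$stages[["lifetable"]] <- list(ok = FALSE, seconds = 0,
                                               error = "fit stage missing")
        status <- 1L
      } else {
        run_stage("lifetable", function() {
          boot <- if (config$lifetable_ci) {
            list(B = config$bootstrap_B, seed = config$seed)
          }
          lt <- life_table(fit, cohort, index_ages = config$index_ages,
                           max_age = config$max_age, step = config$step,
                           window = config$window, boot = boot)
          utils::write.csv(lt, art("lifetable.csv"), row.names = FALSE,
                           na = "")
          lt
        })
      }
    } else if (stage == "cox") {
      run_stage("cox", function() {
        if (!is.null(imputations)) {
          tabs <- lapply(imputations, function(ch) {
            cox_model_suite(prepare_onset_dataset(ch))
          })
          tab <- pool_results(tabs)
        } else {
          tab <- cox_model_suite(prepare_onset_dataset(cohort))
        }
        utils::write.csv(tab, art("cox_models.csv"), row.names = FALSE,
                         na = "")
        tab
      })
    }
  }
  files <- setdiff(list.files(config$outdir, full.names = TRUE),
                   art("manifest.json"))
  manifest$files <- lapply(files, function(f) {
    list(name = basename(f), md5 = unname(tools::md5sum(f)),
         bytes = file.size(f))
  })
  manifest$status <- status
  jsonlite::write_json(manifest, art("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(list(status = status, manifest = manifest))
}
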