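#' Read a long-format dataset from CSV
#'
#' One row per observation occasion; columns are the group id, the outcome
#' columns and the covariates. Empty cells and `NA` are read as missing.
#' Row order is preserved (it fixes the within-group row order of the design
#' matrices).
#'
#' @param path Path to a CSV file with a header row.
#' @return A data.frame.
#' @export
read_long_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (file.size(path) == 0) stop("empty file: ", path)
  out <- tryCatch(
    utils::read.csv(path, stringsAsFactors = FALSE, na.strings = c("NA", "")),
    error = function(e) stop("malformed CSV '", path, "': ",
                             conditionMessage(e)),
    warning = function(w) stop("malformed CSV '", path, "': ",
                               conditionMessage(w)))
  if (nrow(out) == 0L) stop("no data rows in ", path)
  out
}

#' Write a long-format dataset to CSV
#'
#' Inverse of [read_long_csv()]: missing values become empty cells.
#'
#' @param data A data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_long_csv <- function(data, path) {
  utils::write.csv(data, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read a model specification from a YAML configuration file
#'
#' The file names the grouping column and, per outcome, the fixed- and
#' random-effect covariates:
#' ```yaml
#' group: subject
#' outcomes:
#'   - name: weight
#'     fixed: [sex, Nscore, age]
#'     random: [Nscore]
#'   - name: height
#'     fixed: [sex, Nscore, age]
#'     random: [Nscore]
#' ```
#'
#' @param path Path to the YAML file.
#' @return An [mvlmm_spec()].
#' @export
read_model_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$group) || is.null(cfg$outcomes))
    stop("model configuration must provide 'group' and 'outcomes'")
  outcomes <- lapply(cfg$outcomes, function(o) {
    if (is.null(o$name)) stop("every outcome needs a 'name'")
    outcome_spec(o$name,
                 fixed = unlist(o$fixed) %||% character(),
                 random = unlist(o$random) %||% character())
  })
  mvlmm_spec(outcomes, group = cfg$group)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# minimal --flag value parser; flags without a following value become TRUE
parse_cli_args <- function(args) {
  out <- list()
  i <- 1L
  while (i <= length(args)) {
    a <- args[i]
    if (!startsWith(a, "--")) stop("unexpected argument: ", a)
    key <- substring(a, 3L)
    if (i < length(args) && !startsWith(args[i + 1L], "--")) {
      out[[key]] <- args[i + 1L]
      i <- i + 2L
    } else {
      out[[key]] <- TRUE
      i <- i + 1L
    }
  }
  out
}

cli_usage <- function() {
  cat("usage: mvlmm <command> [--options]\n",
      "commands:\n",
      "  fit         --data FILE --model FILE [--out DIR] [--tol X] [--max-iter K]\n",
      "  test        --data FILE --model FILE [--out DIR] [--bartlett] [--B K] [--seed S]\n",
      "  simulate    --out DIR [--n K] [--N K] [--rho X] [--seed S]\n",
      "  bias-study  --out DIR [--n K] [--N K] [--reps R] [--seed S]\n",
      "  mse-study   --out DIR [--n-grid a,b] [--N-grid a,b] [--reps R] [--seed S]\n",
      "  null-study  --out DIR [--N-grid a,b] [--reps R] [--seed S]\n",
      "  power-study --out DIR [--rho-grid a,b] [--n K] [--N K] [--reps R] [--seed S]\n",
      "  screen      --data FILE --model FILE [--out DIR] [--seed S]\n", sep = "")
}

cli_log <- function(dir, lines) {
  writeLines(lines, file.path(dir, "run.log"))
}

num_grid <- function(x, default) {
  if (is.null(x)) return(default)
  as.numeric(strsplit(x, ",")[[1]])
}

#' Command-line entry point
#'
#' Thin dispatcher over the package functions; installed alongside the
#' package as the script `cli/mvlmm.R`. Every output directory receives the
#' result files (JSON/CSV/Newick) plus a `run.log` recording the seed,
#' tolerances and convergence diagnostics of the run.
#'
#' @param args Character vector of command-line arguments (first element the
#'   subcommand).
#' @return Integer exit status (0 on success, 2 on usage errors), invisibly.
#' @export
mvlmm_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (length(args) == 0L) { cli_usage(); return(invisible(2L)) }
  cmd <- args[1L]
  known <- c("fit", "test", "simulate", "bias-study", "mse-study",
             "null-study", "power-study", "screen")
  if (!cmd %in% known) { cli_usage(); return(invisible(2L)) }
  opts <- tryCatch(parse_cli_args(args[-1L]),
                   error = function(e) { cli_usage(); NULL })
  if (is.null(opts)) return(invisible(2L))
  status <- tryCatch({ run_cli_command(cmd, opts); 0L },
                     error = function(e) {
                       message("error: ", conditionMessage(e))
                       1L
                     })
  invisible(status)
}

run_cli_command <- function(cmd, opts) {
  out_dir <- opts$out %||% "."
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- if (!is.null(opts$seed)) as.integer(opts$seed) else NULL
  options <- em_options(tol = as.numeric(opts$tol %||% 1e-5),
                        max_iter = as.integer(opts[["max-iter"]] %||% 5000L))
  header <- c(paste("command:", cmd),
              paste("seed:", seed %||% "none"),
              paste("tol:", options$tol),
              paste("max_iter:", options$max_iter),
              paste("package: mvlmmcor", as.character(utils::packageVersion("mvlmmcor"))))

  if (cmd %in% c("fit", "test", "screen")) {
    if (is.null(opts$data) || is.null(opts$model))
      stop("'", cmd, "' needs --data and --model")
    dat <- read_long_csv(opts$data)
    spec <- read_model_config(opts$model)
  }

  if (cmd == "fit") {
    fit <- fit_em(build_designs(dat, spec), options = options)
    write_fit_json(fit, file.path(out_dir, "fit.json"))
    utils::write.csv(ranef_table(fit), file.path(out_dir, "ranef.csv"),
                     row.names = FALSE)
    cli_log(out_dir, c(header,
                       paste("iterations:", fit$iterations),
                       paste("converged:", fit$converged),
                       paste("loglik trace:",
                             paste(format(fit$loglik_trace), collapse = " "))))
  } else if (cmd == "test") {
    bart <- if (isTRUE(opts$bartlett) || identical(opts$bartlett, "true"))
      "bootstrap" else "none"
    tst <- bivariate_correlation_test(dat, spec, options = options,
                                      bartlett = bart,
                                      B = as.integer(opts$B %||% 200L),
                                      seed = seed)
    rep_obj <- tst[c("S", "df", "p_asymptotic", "loglik_H0", "loglik_H1",
                     "E_S_H0", "S_bartlett", "p_bartlett", "B", "outcomes")]
    rep_obj$seed <- seed
    rep_obj$tol <- options$tol
    jsonlite::write_json(rep_obj, file.path(out_dir, "test.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    cli_log(out_dir, c(header,
                       paste("S:", tst$S), paste("p:", tst$p_asymptotic),
                       paste("H1 iterations:", tst$fit_H1$iterations),
                       paste("H1 converged:", tst$fit_H1$converged),
                       paste("H1 loglik trace:",
                             paste(format(tst$fit_H1$loglik_trace),
                                   collapse = " "))))
  } else if (cmd == "simulate") {
    cfg <- sim_config(n = as.integer(opts$n %||% 300L),
                      N = as.integer(opts$N %||% 5000L),
                      gamma = gamma_params(rho = as.numeric(opts$rho %||% 0.8)),
                      seed = seed)
    d <- simulate_bivariate(cfg)
    write_long_csv(d, file.path(out_dir, "simulated.csv"))
    cli_log(out_dir, c(header, paste("n:", cfg$n), paste("N:", cfg$N),
                       paste("rho:", cfg$gamma$rho)))
  } else if (cmd == "bias-study") {
    st <- bias_study(sim_config(n = as.integer(opts$n %||% 300L),
                                N = as.integer(opts$N %||% 5000L)),
                     R = as.integer(opts$reps %||% 200L), seed = seed,
                     options = options)
    utils::write.csv(data.frame(parameter = names(st$truth),
                                truth = st$truth, mean = st$mean,
                                sd = st$sd, bias = st$bias),
                     file.path(out_dir, "bias.csv"), row.names = FALSE)
    utils::write.csv(st$gamma_bias, file.path(out_dir, "gamma_bias.csv"),
                     row.names = FALSE)
    cli_log(out_dir, c(header, paste("effective R:", st$R)))
  } else if (cmd == "mse-study") {
    st <- mse_study(n_values = as.integer(num_grid(opts[["n-grid"]], c(50, 100))),
                    N_values = as.integer(num_grid(opts[["N-grid"]], c(600, 1000))),
                    R = as.integer(opts$reps %||% 50L), seed = seed,
                    options = options)
    utils::write.csv(st, file.path(out_dir, "mse.csv"), row.names = FALSE)
    cli_log(out_dir, header)
  } else if (cmd == "null-study") {
    st <- null_distribution_study(
      N_values = as.integer(num_grid(opts[["N-grid"]], c(500, 2000))),
      reps = as.integer(opts$reps %||% 200L), seed = seed, options = options)
    utils::write.csv(st, file.path(out_dir, "null_study.csv"), row.names = FALSE)
    cli_log(out_dir, header)
  } else if (cmd == "power-study") {
    st <- power_study(rho_values = num_grid(opts[["rho-grid"]], c(0.2, 0.3)),
                      n = as.integer(opts$n %||% 300L),
                      N = as.integer(opts$N %||% 3000L),
                      reps = as.integer(opts$reps %||% 200L), seed = seed,
                      options = options)
    utils::write.csv(st, file.path(out_dir, "power.csv"), row.names = FALSE)
    cli_log(out_dir, header)
  } else if (cmd == "screen") {
    pw <- pairwise_tests(dat, spec, options = options)
    utils::write.csv(pw$results, file.path(out_dir, "pairs.csv"),
                     row.names = FALSE)
    tree <- cluster_outcomes(pw)
    writeLines(tree$newick, file.path(out_dir, "tree.nwk"))
    cli_log(out_dir, c(header, paste("pairs:", pw$n_pairs)))
  }
  invisible(NULL)
}
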