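# File input/output and the command-line entry point. Data matrices are
# wide-format CSV: a header row of item labels and one row per person;
# missing values are empty fields or NA.

#' Read a wide-format data matrix from CSV
#'
#' @param path CSV file, persons in rows and items in columns, with a
#'   header row.
#' @return numeric matrix (missing values as `NA`).
#' @export
read_matrix_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  as.matrix(utils::read.csv(path, header = TRUE, check.names = FALSE))
}

#' Write the posterior draws of a fit to CSV files
#'
#' One CSV per parameter block (rows are iterations) plus a JSON manifest
#' of the run configuration, so a run is fully reproducible and can be
#' post-processed with generic MCMC tooling.
#'
#' @param object a `jirt` or `jirtq` fit.
#' @param dir output directory (created if needed).
#' @return invisibly, the files written.
#' @export
write_chains_csv <- function(object, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  files <- character(0)
  for (nm in names(object$draws)) {
    ch <- object$draws[[nm]]
    if (length(dim(ch)) == 3)
      ch <- matrix(ch, nrow = dim(ch)[1])
    if (is.null(dim(ch))) ch <- matrix(ch, ncol = 1)
    f <- file.path(dir, paste0("chain_", nm, ".csv"))
    utils::write.csv(ch, f, row.names = FALSE)
    files <- c(files, f)
  }
  manifest <- list(N = object$N, K = object$K, XG = object$XG,
                   burnin = object$burnin, seed = object$seed,
                   class = class(object)[1])
  for (fld in c("ident", "guess", "par1", "par2", "td", "WL",
                "trend", "quadratic"))
    if (!is.null(object[[fld]])) manifest[[fld]] <- object[[fld]]
  f <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, f, auto_unbox = TRUE, digits = NA)
  invisible(c(files, f))
}

#' Write the person/item fit report of a residual run to CSV
#'
#' @param object a `jirt` fit run with `residual = TRUE`.
#' @param dir output directory.
#' @return invisibly, the files written.
#' @export
write_fit_report <- function(object, dir) {
  if (is.null(object$fit)) stop("fit was run without residual = TRUE")
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  f1 <- file.path(dir, "person_fit.csv")
  utils::write.csv(person_fit(object), f1, row.names = FALSE)
  f2 <- file.path(dir, "item_fit.csv")
  utils::write.csv(item_fit(object), f2, row.names = FALSE)
  f3 <- file.path(dir, "cell_outlier_rt.csv")
  utils::write.csv(object$fit$EAPresid, f3, row.names = FALSE)
  f4 <- file.path(dir, "cell_outlier_ra.csv")
  utils::write.csv(object$fit$EAPresidA, f4, row.names = FALSE)
  smry <- list(ndraws = object$fit$ndraws,
               pct_flagged_rt = 100 * mean(object$fit$EAPCP1 >=
                                             object$fitcfg$flag_probability),
               pct_flagged_ra = 100 * mean(object$fit$EAPCP2 >=
                                             object$fitcfg$flag_probability),
               pct_flagged_joint = 100 * mean(object$fit$EAPCP3 >=
                                                object$fitcfg$flag_probability))
  f5 <- file.path(dir, "fit_summary.json")
  jsonlite::write_json(smry, f5, auto_unbox = TRUE, digits = NA)
  invisible(c(f1, f2, f3, f4, f5))
}

# ---- command-line interface -------------------------------------------

parse_cli_args <- function(args) {
  out <- list()
  for (a in args) {
    if (grepl("^--[A-Za-z0-9_]+=", a)) {
      key <- sub("^--([A-Za-z0-9_]+)=.*$", "\\1", a)
      val <- sub("^--[A-Za-z0-9_]+=", "", a)
      out[[key]] <- val
    } else if (grepl("^--", a)) {
      out[[sub("^--", "", a)]] <- "TRUE"
    } else stop("unrecognized argument: ", a)
  }
  out
}

cli_num <- function(opt, key, default) {
  if (is.null(opt[[key]])) default else as.numeric(opt[[key]])
}
cli_flag <- function(opt, key, default = FALSE) {
  if (is.null(opt[[key]])) default else toupper(opt[[key]]) %in%
    c("TRUE", "1", "YES")
}

#' Command-line entry point
#'
#' Subcommands: `simulate` (write a synthetic dataset), `fit` (constant
#' working speed), `fitq` (differential working speed), `summarize`
#' (posterior summary of stored chains is recomputed by refitting is not
#' supported; summarizes a fit written by `fit`), `diagnose` (chain
#' diagnostics). All options are `--key=value`; see the package vignette
#' for the full list. Returns (invisibly) 0 on success; malformed input
#' raises an error.
#'
#' @param args character vector, default `commandArgs(trailingOnly=TRUE)`.
#' @return invisibly, 0.
#' @export
jirt_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (length(args) == 0)
    stop("usage: jirt <simulate|fit|fitq|diagnose> --key=value ...")
  cmd <- args[1]
  opt <- parse_cli_args(args[-1])
  seed <- as.integer(cli_num(opt, "seed", 1))
  outdir <- opt$out %||% "."

  if (cmd == "simulate") {
    sim <- jirt_sim(N = cli_num(opt, "N", 200), K = cli_num(opt, "K", 20),
                    guess = cli_flag(opt, "guess"), seed = seed)
    mar <- cli_num(opt, "mar", 0)
    if (mar > 0) sim <- apply_missing_design(sim, mar_rate = mar)
    write_jirt_sim(sim, outdir)
    message("simulated dataset written to ", outdir)
    return(invisible(0))
  }

  if (cmd %in% c("fit", "fitq")) {
    if (is.null(opt$Y) || is.null(opt$RT))
      stop("'--Y=' and '--RT=' input files are required")
    Y <- read_matrix_csv(opt$Y)
    RT <- read_matrix_csv(opt$RT)
    rd <- function(key) if (is.null(opt[[key]])) NULL
                        else read_matrix_csv(opt[[key]])
    if (cmd == "fit") {
      f <- jirt(Y, RT, XG = cli_num(opt, "XG", 1000),
                burnin = cli_num(opt, "burnin", 10),
                ident = cli_num(opt, "ident", 2),
                guess = cli_flag(opt, "guess"),
                par1 = cli_flag(opt, "par1"),
                td = cli_flag(opt, "td", TRUE),
                WL = cli_flag(opt, "WL"),
                residual = cli_flag(opt, "residual"),
                XGresid = cli_num(opt, "XGresid", 1000),
                XPA = rd("XPA"), XPT = rd("XPT"),
                XIA = rd("XIA"), XIT = rd("XIT"),
                MBDY = rd("MBDY"), MBDT = rd("MBDT"),
                log_rt = cli_flag(opt, "log_rt", TRUE),
                seed = seed)
      if (!is.null(f$fit)) write_fit_report(f, outdir)
    } else {
      f <- jirtq(Y, RT, order = rd("order"),
                 XG = cli_num(opt, "XG", 1000),
                 burnin = cli_num(opt, "burnin", 10),
                 td = cli_flag(opt, "td", TRUE),
                 trend = cli_flag(opt, "trend", TRUE),
                 quadratic = cli_flag(opt, "quadratic", TRUE),
                 MBDY = rd("MBDY"), MBDT = rd("MBDT"),
                 seed = seed)
    }
    write_chains_csv(f, outdir)
    s <- summary(f)
    utils::write.csv(cbind(item = seq_len(f$K), round(s$items, 5)),
                     file.path(outdir, "summary_items.csv"),
                     row.names = FALSE)
    message("chains and summaries written to ", outdir)
    return(invisible(0))
  }

  if (cmd == "diagnose") {
    if (is.null(opt$chain)) stop("'--chain=' input file is required")
    ch <- read_matrix_csv(opt$chain)
    rows <- lapply(seq_len(ncol(ch)), function(j) {
      m <- mcse(ch[, j])
      data.frame(column = j, mean = mean(ch[, j]), sd = m$sd,
                 naive_se = m$naive_se, mcse = m$mcse, ess = m$ess,
                 geweke_z = geweke(ch[, j]))
    })
    tab <- do.call(rbind, rows)
    f <- file.path(outdir, "diagnostics.csv")
    utils::write.csv(tab, f, row.names = FALSE)
    message("diagnostics written to ", f)
    return(invisible(0))
  }
  stop("unknown subcommand: ", cmd)
}
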