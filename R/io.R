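# Plain-text curve and table I/O plus the YAML run configuration. Curve
# files: columns q R [dR] [dq], '#' comments, whitespace- or
# comma-delimited. Writers emit 16 significant digits so a write-then-read
# round trip is lossless for practical purposes.

#' Read a reflectivity curve file
#'
#' Parses a plain-text file with columns `q R [dR] [dq]` (comment lines
#' start with `#`; whitespace- and comma-delimited dialects are detected
#' automatically). Rows with non-positive reflectivity - which cannot enter
#' the logarithmic part of the fit score - are dropped with a warning and
#' the count is kept in the `n_dropped` attribute; q is sorted ascending.
#' When a fourth (absolute dq) column is present it overrides the global
#' `dq_over_q` pointwise.
#'
#' @param path File path.
#' @param rho_fronting,rho_solvent Fronting and solvent SLDs
#'   (\eqn{\mathrm{\AA}^{-2}}).
#' @param dq_over_q Fractional resolution used when the file has no dq
#'   column (default 0.10).
#' @param label Curve label; default the file name.
#' @param sld_units Set to `"1e-6"` if the file's SLD-bearing metadata uses
#'   units of \eqn{10^{-6}\,\mathrm{\AA}^{-2}} for `rho_fronting` /
#'   `rho_solvent` (they are then rescaled).
#' @return A [contrast_curve()].
#' @export
read_curve <- function(path, rho_fronting, rho_solvent, dq_over_q = 0.1,
                       label = NULL, sld_units = c("A^-2", "1e-6")) {
  sld_units <- match.arg(sld_units)
  if (!file.exists(path)) stop(sprintf("curve file not found: %s", path))
  if (sld_units == "1e-6") {
    rho_fronting <- rho_fronting * 1e-6
    rho_solvent <- rho_solvent * 1e-6
  }
  lines <- readLines(path, warn = FALSE)
  body <- grep("^\\s*(#|$)", lines, invert = TRUE, value = TRUE)
  if (!length(body)) stop(sprintf("no data rows in %s", path))
  sep <- if (any(grepl(",", body))) "," else ""
  df <- tryCatch(
    read.table(text = body, sep = sep, header = FALSE,
               strip.white = TRUE, comment.char = "#"),
    error = function(e) stop(sprintf("cannot parse %s: %s", path,
                                     conditionMessage(e))))
  df <- df[, vapply(df, is.numeric, logical(1)), drop = FALSE]
  if (ncol(df) < 2) stop(sprintf("%s has fewer than 2 numeric columns", path))
  q <- df[[1]]; R <- df[[2]]
  dR <- if (ncol(df) >= 3) df[[3]] else NULL
  dqq <- dq_over_q
  if (ncol(df) >= 4) {
    dq <- df[[4]]
    dqq <- ifelse(q > 0, dq / q, dq_over_q)
    dqq <- median(dqq[is.finite(dqq) & dqq > 0])
  }
  if (is.null(label)) label <- sub("\\.[^.]*$", "", basename(path))
  contrast_curve(q, R, dR = dR, dq_over_q = dqq,
                 rho_fronting = rho_fronting,
                 rho_solvent = rho_solvent, label = label)
}

# full-precision text rendering of a table's columns
fmt_cols <- function(df) {
  as.data.frame(lapply(df, function(col)
    if (is.numeric(col)) sprintf("%.15e", col) else as.character(col)),
    check.names = FALSE)
}

#' Write a reflectivity curve
#'
#' @param curve A [contrast_curve()] or data frame with columns `q`, `R`
#'   (and optionally `dR`).
#' @param path Output path.
#' @param comment Extra header lines (written with a `#` prefix).
#' @return `path`, invisibly.
#' @export
write_curve <- function(curve, path, comment = character()) {
  if (inherits(curve, "contrast_curve")) {
    df <- data.frame(q = curve$q, R = curve$R)
    if (!is.null(curve$dR)) df$dR <- curve$dR
    comment <- c(sprintf("label: %s", curve$label),
                 sprintf("rho_fronting: %.12g", curve$rho_fronting),
                 sprintf("rho_solvent: %.12g", curve$rho_solvent),
                 sprintf("dq_over_q: %.12g", curve$dq_over_q), comment)
  } else df <- curve
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste("#", comment),
               paste("#", paste(names(df), collapse = "\t"))), con)
  write.table(fmt_cols(df),
              con, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Write any table as tab-separated text with a commented header
#'
#' @param df Data frame.
#' @param path Output path.
#' @param comment Extra header lines.
#' @return `path`, invisibly.
#' @export
write_profile_table <- function(df, path, comment = character()) {
  con <- file(path, "w")
  on.exit(close(con))
  if (length(comment)) writeLines(paste("#", comment), con)
  writeLines(paste("#", paste(names(df), collapse = "\t")), con)
  write.table(fmt_cols(df),
              con, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Read a run configuration
#'
#' YAML schema (see the package README): `contrasts:` list of
#' `{file, label, rho_fronting, rho_solvent, dq_over_q}`, optional `D`
#' (\eqn{\mathrm{\AA}}) or `ift: {auto: true, D_grid: [lo, hi, step]}`,
#' `bounds: {rho_min, rho_max}`, `constraints:` list of
#' `{z_range: [lo, hi], kind, value}`, `schedule:` overrides, `n_runs`,
#' `seed`, `fast`, `sld_units`.
#'
#' @param path YAML file.
#' @return Validated list with the config hash (`md5`) attached.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("config file not found: %s", path))
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$contrasts) || !length(cfg$contrasts))
    stop("config must list at least one contrast")
  for (ct in cfg$contrasts) {
    if (is.null(ct$file)) stop("each contrast needs a 'file'")
    if (is.null(ct$rho_fronting) || is.null(ct$rho_solvent))
      stop("each contrast needs rho_fronting and rho_solvent")
  }
  if (is.null(cfg$D) && is.null(cfg$ift$auto))
    stop("config needs either a fixed 'D' or 'ift: {auto: true, ...}'")
  cfg$md5 <- unname(tools::md5sum(path))
  cfg$path <- path
  cfg
}

load_config_contrasts <- function(cfg) {
  units <- if (identical(cfg$sld_units, "1e-6")) "1e-6" else "A^-2"
  base <- dirname(cfg$path)
  lapply(cfg$contrasts, function(ct) {
    p <- ct$file
    if (!file.exists(p)) p <- file.path(base, ct$file)
    read_curve(p, ct$rho_fronting, ct$rho_solvent,
               dq_over_q = if (is.null(ct$dq_over_q)) 0.1 else ct$dq_over_q,
               label = ct$label, sld_units = units)
  })
}
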