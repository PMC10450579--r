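## Tabular and configuration I/O.
##
## CSV dialects (one header line, decimal point, comma separator):
##   thermogram: injection_index, injection_volume_uL, heat_uJ
##   titration:  ligand_total_nM, signal
##   grid:       o_nM, a_nM, k_obs        (long format)
## Model parameter files are flat key-value YAML with keys k_eq,
## kd_o_active, kd_o_inactive, kd_a_active, kd_a_inactive, coupling_active,
## coupling_inactive (concentrations in nM; "Inf"/".inf" = non-binder).

.ddk_table_columns <- list(
  thermogram = c("injection_index", "injection_volume_uL", "heat_uJ"),
  titration = c("ligand_total_nM", "signal"),
  grid = c("o_nM", "a_nM", "k_obs")
)

.ddk_parse_error <- function(msg) {
  stop(errorCondition(msg, class = c("ddk_parse_error", "error", "condition")))
}

#' Read a titration table
#'
#' Reads and validates one of the package's CSV dialects.  Columns may
#' appear in any order; missing or non-numeric cells and (for `titration`)
#' a non-monotone concentration axis are reported as structured parse
#' errors naming the offending row and column.
#'
#' @param path File path.
#' @param kind `"thermogram"`, `"titration"` or `"grid"`.
#' @return For `"thermogram"`, a list with the validated data.frame (`data`)
#'   usable with [itc_thermogram()]; for `"titration"`, a
#'   [titration_curve()]; for `"grid"`, the long-format data.frame.
#' @export
read_titration_table <- function(path, kind = c("thermogram", "titration", "grid")) {
  kind <- match.arg(kind)
  if (!file.exists(path)) .ddk_parse_error(paste0("file not found: ", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  want <- .ddk_table_columns[[kind]]
  missing_cols <- setdiff(want, names(df))
  if (length(missing_cols)) {
    .ddk_parse_error(paste0("missing column(s): ",
                            paste(missing_cols, collapse = ", ")))
  }
  df <- df[want]
  if (nrow(df) == 0) .ddk_parse_error("table has a header but no rows")
  for (col in want) {
    v <- df[[col]]
    if (!is.numeric(v)) {
      bad <- which(is.na(suppressWarnings(as.numeric(v))))[1]
      .ddk_parse_error(sprintf("non-numeric cell in column '%s', row %d", col, bad))
    }
    if (anyNA(v)) {
      .ddk_parse_error(sprintf("missing value in column '%s', row %d",
                               col, which(is.na(v))[1]))
    }
  }
  switch(kind,
    thermogram = {
      if (any(df$injection_volume_uL <= 0)) {
        .ddk_parse_error(sprintf(
          "non-positive injection volume in row %d",
          which(df$injection_volume_uL <= 0)[1]))
      }
      df
    },
    titration = {
      bad <- which(diff(df$ligand_total_nM) <= 0)
      if (length(bad)) {
        .ddk_parse_error(sprintf(
          "column 'ligand_total_nM' is not strictly increasing at row %d",
          bad[1] + 1))
      }
      if (any(df$ligand_total_nM < 0)) {
        .ddk_parse_error("negative concentration in column 'ligand_total_nM'")
      }
      titration_curve(df$ligand_total_nM, df$signal)
    },
    grid = df
  )
}

#' Write a titration table
#'
#' Inverse of [read_titration_table()].  Accepts a `ddk_titration_curve`, a
#' `ddk_itc_thermogram` together with its protocol, or a `ddk_synergy_grid`
#' (written in long format).
#'
#' @param x Object to write.
#' @param path Output file path.
#' @param protocol Required when `x` is a thermogram (supplies injection
#'   volumes).
#' @return `path`, invisibly.
#' @export
write_titration_table <- function(x, path, protocol = NULL) {
  df <- if (inherits(x, "ddk_titration_curve")) {
    data.frame(ligand_total_nM = x$ligand_total, signal = x$signal)
  } else if (inherits(x, "ddk_itc_thermogram")) {
    stopifnot(inherits(protocol, "ddk_itc_protocol"))
    data.frame(injection_index = seq_along(x$heats),
               injection_volume_uL = protocol$injection_volumes,
               heat_uJ = x$heats)
  } else if (inherits(x, "ddk_synergy_grid")) {
    data.frame(
      o_nM = rep(x$o_grid, each = length(x$a_grid)),
      a_nM = rep(x$a_grid, times = length(x$o_grid)),
      k_obs = as.vector(x$k_obs)
    )
  } else {
    stop("unsupported object for write_titration_table()")
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a linkage model parameter file
#'
#' Flat key-value YAML; unknown keys are rejected.  Missing affinity keys
#' default to `Inf` (non-binder) and missing couplings to 1, matching
#' [ddk_model()].
#'
#' @param path YAML file path.
#' @return A [ddk_model()].
#' @export
read_model_file <- function(path) {
  if (!file.exists(path)) .ddk_parse_error(paste0("file not found: ", path))
  cfg <- yaml::read_yaml(path)
  allowed <- c("k_eq", "kd_o_active", "kd_o_inactive",
               "kd_a_active", "kd_a_inactive",
               "coupling_active", "coupling_inactive")
  unknown <- setdiff(names(cfg), allowed)
  if (length(unknown)) {
    .ddk_parse_error(paste0("unknown key(s) in model file: ",
                            paste(unknown, collapse = ", ")))
  }
  if (!"k_eq" %in% names(cfg)) .ddk_parse_error("model file must set k_eq")
  cfg <- lapply(cfg, function(v) {
    if (is.character(v)) v <- suppressWarnings(as.numeric(sub("^\\.?[Ii]nf$", "Inf", v)))
    if (is.na(v)) .ddk_parse_error("non-numeric value in model file")
    v
  })
  do.call(ddk_model, cfg)
}
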