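## CSV / JSON / YAML serialization.  CSV dialect: comma separator, header
## row required, "." decimal, empty cell or NA = missing; numeric fields are
## written with 17 significant digits so values round-trip exactly.

#' Read a rectangular trial dataset from CSV
#'
#' @param path file path; must have a header row.  Empty cells and
#'   \code{NA} are read as missing.
#' @return A data frame.
#' @export
read_trial_csv <- function(path) {
  if (!file.exists(path))
    stop_spslreg(paste0("cannot read data file: ", path), "spslreg_io_error")
  utils::read.csv(path, na.strings = c("", "NA"), check.names = FALSE)
}

#' Write a rectangular dataset to CSV with round-trip precision
#'
#' @param df a data frame.
#' @param path output file path.
#' @export
write_trial_csv <- function(df, path) {
  out <- as.data.frame(df)
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) {
      s <- sprintf("%.17g", out[[j]])
      s[is.na(out[[j]])] <- NA_character_
      out[[j]] <- s
    }
  }
  utils::write.table(out, path, sep = ",", quote = FALSE, na = "",
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

# Read a config as YAML or JSON by extension (YAML parses JSON too).
read_config <- function(path) {
  if (!file.exists(path))
    stop_spslreg(paste0("cannot read config file: ", path), "spslreg_io_error")
  tryCatch({
    if (grepl("\\.json$", path, ignore.case = TRUE))
      jsonlite::read_json(path, simplifyVector = TRUE)
    else
      # keep keys/values like "n" or "y" textual instead of YAML-1.1 booleans
      yaml::read_yaml(path, handlers = list(
        "bool#no" = function(x) x, "bool#yes" = function(x) x))
  }, error = function(e)
    stop_spslreg(paste0("malformed config: ", conditionMessage(e)),
                 "spslreg_config_error"))
}

# Serializable representation of an estimator fit.
fit_to_list <- function(fit) {
  out <- list(method = fit$method,
              coefficients = as.list(coef(fit)),
              covariance = unname(apply(vcov(fit), 1, as.list)),
              coefficient_names = names(coef(fit)),
              sigma2 = fit$sigma2,
              dof = fit$dof)
  if (!is.null(fit$diagnostics)) {
    d <- fit$diagnostics
    out$alpha_hat <- d$alpha_hat
    out$tau_hat <- d$tau_hat
    out$dist_sq <- d$dist_sq
    out$degenerate <- d$degenerate
  }
  out
}

write_json_out <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}
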