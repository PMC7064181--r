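# Run configuration and provenance plumbing shared by the analysis
# drivers: YAML/JSON config loading with strict key validation, seeded
# runs, and JSON run manifests recording parameters alongside outputs.

#' Load and validate a run configuration
#'
#' Reads a YAML or JSON configuration file (or takes an inline list),
#' fills defaults, and rejects unknown keys. The returned configuration
#' carries a provenance block (package version, seed, timestamp) suitable
#' for embedding in a run manifest.
#'
#' @param config path to a YAML/JSON file, or a named list of overrides.
#' @param defaults named list of known keys and their default values.
#' @param required character vector of keys that must be present.
#' @return a named list of class \code{run_config} with all defaults
#'   filled and a \code{provenance} attribute.
#' @export
load_config <- function(config, defaults = list(), required = character()) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- if (grepl("\\.json$", config, ignore.case = TRUE))
      jsonlite::read_json(config, simplifyVector = TRUE)
    else yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown) > 0L)
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  missing <- setdiff(required, names(config))
  if (length(missing) > 0L)
    stop("missing required configuration key(s): ",
         paste(missing, collapse = ", "))
  out <- utils::modifyList(defaults, config)
  attr(out, "provenance") <- list(
    package = "hypermutr",
    version = as.character(utils::packageVersion("hypermutr")),
    seed = out$seed,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  class(out) <- c("run_config", class(out))
  out
}

#' Write a JSON run manifest next to an output file
#'
#' @param cfg a \code{run_config} (or plain named list of parameters).
#' @param outputs character vector of files the run produced.
#' @param path manifest path (JSON).
#' @export
write_manifest <- function(cfg, outputs, path) {
  manifest <- list(parameters = unclass(cfg),
                   provenance = attr(cfg, "provenance"),
                   outputs = outputs)
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Write a tidy TSV
#'
#' @param x data.frame.
#' @param path output path.
#' @export
write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a tidy TSV
#'
#' @param path input path.
#' @return data.frame.
#' @export
read_tsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Read a fluctuation-assay count table
#'
#' @param path TSV with columns \code{clone} (optional), \code{Nt} and
#'   \code{r}.
#' @return a named list of \code{\link{fluctuation_experiment}}s, one per
#'   clone (a single unnamed experiment if no clone column).
#' @export
read_fluctuation_tsv <- function(path) {
  tab <- read_tsv(path)
  stopifnot(all(c("Nt", "r") %in% names(tab)))
  if (is.null(tab$clone)) tab$clone <- "clone"
  lapply(split(tab, tab$clone),
         function(d) fluctuation_experiment(d$Nt, d$r))
}

#' Read a per-clone SNP table
#'
#' Expects columns \code{clone}, \code{position} (1-based, converted to
#' the 0-based internal convention), \code{ref}, \code{alt}, and
#' optionally \code{gene} and \code{effect}.
#'
#' @param path TSV path.
#' @param gm optional \code{\link{genome_model}}; when given, gene and
#'   effect annotations are (re)computed.
#' @return SNP table data.frame with 0-based \code{position}.
#' @export
read_snp_tsv <- function(path, gm = NULL) {
  tab <- read_tsv(path)
  stopifnot(all(c("clone", "position", "ref", "alt") %in% names(tab)))
  tab$position <- tab$position - 1L
  if (!is.null(gm)) tab <- annotate_snps(tab, gm)
  tab
}

#' Write a per-clone SNP table (1-based positions)
#'
#' @param table SNP table with 0-based \code{position}.
#' @param path output TSV.
#' @export
write_snp_tsv <- function(table, path) {
  table$position <- table$position + 1L
  write_tsv(table, path)
}
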