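# Readers and writers for the artifact formats: FASTA sequence sets,
# property-record CSV, Pareto-archive JSON and run configuration YAML.

#' Read amino-acid sequences from FASTA
#'
#' Wraps the Biostrings FASTA reader with strict alphabet validation:
#' only the 20 canonical one-letter codes are accepted (mixed case is
#' uppercased with a warning); any other character is rejected naming the
#' offending record.
#'
#' @param path FASTA file.
#' @return named character vector (possibly empty).
#' @export
read_fasta <- function(path) {
  set_ <- Biostrings::readBStringSet(path)
  if (length(set_) == 0) return(setNames(character(0), character(0)))
  seqs <- as.character(set_)
  if (any(grepl("[a-z]", seqs))) {
    warning("mixed-case FASTA input; residues uppercased")
    seqs <- toupper(seqs)
  }
  for (i in seq_along(seqs)) {
    bad <- setdiff(unique(strsplit(seqs[i], "")[[1]]), AA_ALPHABET)
    if (length(bad) > 0) {
      stop("non-amino-acid character(s) ", paste(bad, collapse = ", "),
           " in record '", names(seqs)[i], "' (record ", i, ")")
    }
  }
  seqs
}

#' Write sequences to FASTA
#'
#' @param seqs named character vector.
#' @param path output file.
#' @param width line width (default 60).
#' @return the path, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 60) {
  if (is.null(names(seqs))) names(seqs) <- paste0("seq", seq_along(seqs))
  set_ <- Biostrings::AAStringSet(seqs)
  Biostrings::writeXStringSet(set_, path, width = width)
  invisible(path)
}

PROPERTY_COLUMNS <- c("id", "B2", "B2_se", "phase_sep", "rho_c", "rho_c_se",
                      "D", "D_se", "provenance")

#' Write / read a property-record table
#'
#' CSV with the standard schema
#' \code{id,B2,B2_se,phase_sep,rho_c,rho_c_se,D,D_se,provenance} (plus a
#' \code{sequence} column when present).
#'
#' @param records property data.frame.
#' @param path CSV file.
#' @return \code{read_property_table} returns the data.frame.
#' @export
write_property_table <- function(records, path) {
  cols <- intersect(c("id", "sequence", PROPERTY_COLUMNS), names(records))
  write.csv(records[, cols], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_property_table
#' @export
read_property_table <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(setdiff(PROPERTY_COLUMNS, "id"), names(df))
  if (length(miss) > 0) {
    stop("property table missing column(s): ", paste(miss, collapse = ", "))
  }
  df$phase_sep <- as.logical(df$phase_sep)
  df
}

#' Serialize / load a Pareto archive as JSON
#'
#' @param archive list as returned by \code{\link{al_archive}} or
#'   \code{\link{planted_front}}.
#' @param path JSON file.
#' @param iteration optional iteration tag.
#' @return \code{read_archive_json} returns the archive list.
#' @export
write_archive_json <- function(archive, path, iteration = NULL) {
  payload <- list(points = archive$points,
                  reference_point = archive$reference,
                  hypervolume = archive$hypervolume,
                  iteration = iteration)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_archive_json
#' @export
read_archive_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$points <- as.data.frame(x$points)
  x
}

#' Read / write a run configuration
#'
#' YAML round-trip of the nested configuration lists (GA, oracle,
#' active-learning settings, seeds).
#'
#' @param config named list.
#' @param path YAML file.
#' @return \code{read_run_config} returns the list.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) yaml::read_yaml(path)

#' Hash of a configuration (stamped into output files)
#'
#' @param config named list.
#' @return short hex digest string.
#' @export
config_hash <- function(config) {
  txt <- paste(deparse(config[order(names(config))]), collapse = "")
  # 31-bit polynomial rolling hash over the serialized text
  h <- 0
  for (b in utf8ToInt(txt)) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}
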