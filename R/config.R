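# Run configuration: a YAML file with `simulation` and `classifier` sections
# mapping directly onto sim_config() / classifier_config() arguments.

#' Read a run configuration from YAML
#'
#' Unknown keys are rejected so typos cannot silently fall back to defaults.
#'
#' @param path YAML file with optional `simulation` and `classifier`
#'   sections.
#' @return list(simulation = [sim_config()], classifier =
#'   [classifier_config()]).
#' @export
read_run_config <- function(path) {
  stopifnot(file.exists(path))
  y <- yaml::read_yaml(path)
  build <- function(args, fun, what) {
    args <- args %||% list()
    bad <- setdiff(names(args), names(formals(fun)))
    if (length(bad)) stop("unknown ", what, " key(s): ",
                          paste(bad, collapse = ", "))
    if (!is.null(args$species)) args$species <- as.character(args$species)
    if (!is.null(args$cds_len_range)) {
      args$cds_len_range <- as.integer(args$cds_len_range)
    }
    do.call(fun, args)
  }
  list(simulation = build(y$simulation, sim_config, "simulation"),
       classifier = build(y$classifier, classifier_config, "classifier"))
}
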