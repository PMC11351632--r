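# Structured-text (YAML) configuration: each config fully describes one
# tube condition (age group, endometriosis, lesion layout overrides),
# the physical parameters and the simulation designs. A model factory
# writes the six canonical configurations (3 ages x normal/endometriosis)
# plus the 3/7/10-lesion appendix-style variants.

#' Serialise a condition to a configuration list
#'
#' @param age_group Age tag.
#' @param with_endometriosis Logical.
#' @param lesion_count 0, 3, 5, 7 or 10.
#' @param overrides Tube overrides (see [build_tube()]).
#' @param params Parameter list; defaults to [default_params()].
#' @return A plain list suitable for [write_config()].
#' @export
make_config <- function(age_group, with_endometriosis = FALSE,
                        lesion_count = if (with_endometriosis) 5L else 0L,
                        overrides = list(),
                        params = default_params(age_group)) {
  list(
    tube = list(age_group = age_group,
                with_endometriosis = with_endometriosis,
                lesion_count = as.integer(lesion_count),
                overrides = overrides),
    params = params[setdiff(names(params), "age_group")],
    design = list(
      sperm = list(n_agents = 10000L, duration = 80, dt = 1),
      oocyte = list(n_agents = 100L, duration = 80, dt = 10)))
}

#' Write a configuration to a YAML file
#' @param config List from [make_config()].
#' @param path Output file.
#' @export
write_config <- function(config, path) {
  # functions/objects in params are reduced to plain lists for YAML
  config <- rapply(config, f = function(x) x, how = "replace")
  yaml::write_yaml(.de_class(config), path)
  invisible(path)
}

.de_class <- function(x) {
  if (is.list(x)) {
    x <- lapply(x, .de_class)
    attributes(x) <- list(names = names(x))
  }
  x
}

#' Read a configuration written by [write_config()]
#' @param path YAML file.
#' @return Configuration list.
#' @export
read_config <- function(path) yaml::read_yaml(path)

#' Build the tube and parameters described by a configuration
#'
#' @param config List from [make_config()] or [read_config()].
#' @return List with elements `tube`, `params`, `design`.
#' @export
build_from_config <- function(config) {
  tc <- config$tube
  params <- default_params(tc$age_group)
  params <- utils::modifyList(params, config$params %||% list())
  params$age_group <- tc$age_group
  # restore sub-model classes lost in YAML round-trips
  if (!inherits(params$sperm$control, "beat_control"))
    params$sperm$control <- do.call(beat_control, params$sperm$control)
  if (!inherits(params$oocyte$model, "oocyte_model"))
    params$oocyte$model <- do.call(
      oocyte_model,
      params$oocyte$model[intersect(names(params$oocyte$model),
                                    names(formals(oocyte_model)))])
  ovr <- config$tube$overrides %||% list()
  if (is.null(ovr$lesion_protrusion_frac))
    ovr$lesion_protrusion_frac <- params$protrusion_frac
  tube <- build_tube(tc$age_group, tc$with_endometriosis,
                     lesion_count = tc$lesion_count %||%
                       (if (tc$with_endometriosis) 5L else 0L),
                     overrides = ovr)
  list(tube = tube, params = params, design = config$design)
}

#' Write the canonical configuration set
#'
#' Writes the six canonical configurations (20s/30s/40s, each normal and
#' with the five-lesion endometriosis layout) and, for the 20s tube, the
#' 3-, 7- and 10-lesion variants.
#'
#' @param dir Output directory (created if needed).
#' @return Character vector of paths written.
#' @export
write_canonical_configs <- function(dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (age in c("20s", "30s", "40s")) {
    for (endo in c(FALSE, TRUE)) {
      f <- file.path(dir, sprintf("%s_%s.yaml", age,
                                  if (endo) "endometriosis" else "normal"))
      write_config(make_config(age, endo), f)
      paths <- c(paths, f)
    }
  }
  for (nl in c(3L, 7L, 10L)) {
    f <- file.path(dir, sprintf("20s_endometriosis_%dlesions.yaml", nl))
    write_config(make_config("20s", TRUE, lesion_count = nl), f)
    paths <- c(paths, f)
  }
  paths
}
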