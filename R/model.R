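#' Construct a muscle element
#'
#' A muscle element is one line of action of the reduced calf model: a maximum
#' isometric force and a constant signed moment arm about each model degree of
#' freedom (DOF). Activation is defined as instantaneous force divided by
#' `f_max`, so `f_max` doubles as the force upper bound in the static
#' optimization.
#'
#' @param name Muscle element name (unique within a model).
#' @param group Anatomical group label, one of `"dorsiflexor"`,
#'   `"plantarflexor"`, `"invertor"`, `"evertor"`, `"toe_flexor"`,
#'   `"toe_extensor"`.
#' @param f_max Maximum isometric force in newtons, strictly positive.
#' @param moment_arms Named numeric vector, one signed moment arm in metres per
#'   DOF. Positive directions: dorsiflexion, inversion, toe (MTP) extension.
#' @return An object of class `muscle_element`.
#' @export
muscle_element <- function(name, group, f_max, moment_arms) {
  if (!is.character(name) || length(name) != 1L || !nzchar(name))
    stop("model schema error: muscle name must be a non-empty string")
  if (!is.numeric(f_max) || length(f_max) != 1L || !is.finite(f_max) || f_max <= 0)
    stop("model validation error: f_max must be > 0 (muscle '", name, "')")
  if (is.null(names(moment_arms)) || any(!nzchar(names(moment_arms))))
    stop("model schema error: moment_arms must be named by DOF")
  if (any(!is.finite(moment_arms)))
    stop("model validation error: non-finite moment arm (muscle '", name, "')")
  if (any(abs(moment_arms) > 0.12))
    stop("model validation error: |moment arm| exceeds 0.12 m (muscle '", name, "')")
  if (all(moment_arms == 0))
    stop("model validation error: muscle '", name, "' spans no DOF")
  structure(
    list(name = name, group = group, f_max = as.numeric(f_max),
         moment_arms = moment_arms),
    class = "muscle_element"
  )
}

.muscle_groups <- c("dorsiflexor", "plantarflexor", "invertor", "evertor",
                    "toe_flexor", "toe_extensor")

#' Construct a model definition
#'
#' Bundles the muscle elements, the ordered DOF list and the segment
#' anthropometry (mass fraction of body mass, centre-of-mass offset from the
#' proximal joint along the segment axis, radius of gyration) into a validated
#' reduced musculoskeletal model.
#'
#' @param muscles List of [muscle_element()] objects (order is preserved and
#'   defines the muscle order of every downstream matrix and table).
#' @param dofs Character vector of DOF identifiers.
#' @param segments Data frame with columns `segment`, `mass_fraction`,
#'   `com_offset_m`, `gyration_radius_m`; must contain rows `foot` and `shank`.
#' @param check_antagonists If `TRUE` (default), require every DOF to be
#'   spanned by at least two muscles with opposite-signed arms so antagonist
#'   co-loading is representable. Disable for deliberately degenerate test
#'   models.
#' @return An object of class `model_definition`.
#' @export
model_definition <- function(muscles, dofs, segments, check_antagonists = TRUE) {
  if (!length(muscles)) stop("model schema error: no muscles")
  if (!length(dofs)) stop("model schema error: no DOFs")
  nm <- vapply(muscles, function(m) m$name, character(1))
  if (anyDuplicated(nm)) stop("model schema error: duplicate muscle names")
  if (anyDuplicated(dofs)) stop("model schema error: duplicate DOF names")
  for (m in muscles) {
    unknown <- setdiff(names(m$moment_arms), dofs)
    if (length(unknown))
      stop("model schema error: muscle '", m$name, "' references unknown DOF '",
           unknown[1], "'")
  }
  need <- c("segment", "mass_fraction", "com_offset_m", "gyration_radius_m")
  if (!is.data.frame(segments) || !all(need %in% names(segments)))
    stop("model schema error: segments table must have columns ",
         paste(need, collapse = ", "))
  if (!all(c("foot", "shank") %in% segments$segment))
    stop("model schema error: segments must include 'foot' and 'shank'")
  model <- structure(
    list(muscles = muscles, dofs = as.character(dofs), segments = segments),
    class = "model_definition"
  )
  if (check_antagonists) {
    R <- moment_arm_matrix(model)$values
    for (j in seq_along(dofs)) {
      if (!(any(R[j, ] > 0) && any(R[j, ] < 0)))
        stop("model validation error: DOF '", dofs[j],
             "' lacks opposite-signed moment arms")
    }
  }
  model
}

#' @export
print.model_definition <- function(x, ...) {
  cat("<model_definition> ", length(x$muscles), " muscles, ",
      length(x$dofs), " DOFs (", paste(x$dofs, collapse = ", "), ")\n", sep = "")
  invisible(x)
}

#' Muscle names of a model
#' @param model A `model_definition`.
#' @return Character vector in model order.
#' @export
muscle_names <- function(model) vapply(model$muscles, function(m) m$name, character(1))

#' Maximum isometric forces of a model
#' @param model A `model_definition`.
#' @return Named numeric vector in model order, newtons.
#' @export
muscle_fmax <- function(model) {
  f <- vapply(model$muscles, function(m) m$f_max, numeric(1))
  names(f) <- muscle_names(model)
  f
}

#' Segment anthropometry lookup
#' @param model A `model_definition`.
#' @param segment Segment name, e.g. `"foot"`.
#' @return One-row data frame of the anthropometry record.
#' @export
segment_params <- function(model, segment) {
  i <- match(segment, model$segments$segment)
  if (is.na(i)) stop("model schema error: unknown segment '", segment, "'")
  model$segments[i, , drop = FALSE]
}

#' Moment-arm matrix of a model
#'
#' Assembles the `n_dof x n_muscle` signed moment-arm matrix `R` used in the
#' moment-balance equality constraints `R F = M` of the static optimization.
#' Entry `(j, i)` is the moment arm of muscle `i` about DOF `j`, zero where the
#' muscle does not span the DOF. Row and column order follow the model
#' definition, so two loads of the same file yield identical matrices.
#'
#' @param model A validated `model_definition`.
#' @return A list of class `moment_arm_matrix` with fields `values` (matrix,
#'   metres), `dof_order` and `muscle_order`.
#' @export
moment_arm_matrix <- function(model) {
  nm <- muscle_names(model)
  R <- matrix(0, nrow = length(model$dofs), ncol = length(nm),
              dimnames = list(model$dofs, nm))
  for (i in seq_along(model$muscles)) {
    arms <- model$muscles[[i]]$moment_arms
    R[names(arms), i] <- as.numeric(arms)
  }
  structure(list(values = R, dof_order = model$dofs, muscle_order = nm),
            class = "moment_arm_matrix")
}

# ---- model file I/O --------------------------------------------------------

.read_section_lines <- function(lines) {
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  sec <- cumsum(grepl("^\\[", lines))
  tags <- sub("^\\[(.*)\\]$", "\\1", lines[grepl("^\\[", lines)])
  out <- list()
  for (k in seq_along(tags)) out[[tags[k]]] <- lines[sec == k & !grepl("^\\[", lines)]
  out
}

.parse_tsv_block <- function(lines, what) {
  if (!length(lines)) stop("model schema error: empty [", what, "] section")
  con <- textConnection(lines)
  on.exit(close(con))
  utils::read.delim(con, header = TRUE, stringsAsFactors = FALSE,
                    check.names = FALSE)
}

#' Load a model definition from a text file
#'
#' The model file is a small UTF-8 text format with three sections: `[dofs]`
#' (one DOF identifier per line), `[muscles]` (tab-separated table with columns
#' `muscle`, `group`, `f_max_N`, then one `r_<dof>_m` column per DOF) and
#' `[segments]` (tab-separated anthropometry table). `#` starts a comment. See
#' the bundled default under `system.file("extdata", "default_model.tsv",
#' package = "calfcontrib")` for a documented example.
#'
#' @param path Path to a model-definition file; defaults to the bundled
#'   17-muscle, 3-DOF calf model.
#' @return A validated `model_definition`.
#' @export
load_model <- function(path = default_model_path()) {
  if (!file.exists(path)) stop("model schema error: file not found: ", path)
  sec <- .read_section_lines(readLines(path, encoding = "UTF-8"))
  for (s in c("dofs", "muscles", "segments"))
    if (is.null(sec[[s]])) stop("model schema error: missing [", s, "] section")
  dofs <- trimws(sec$dofs)
  mus <- .parse_tsv_block(sec$muscles, "muscles")
  need <- c("muscle", "group", "f_max_N")
  if (!all(need %in% names(mus)))
    stop("model schema error: [muscles] needs columns ", paste(need, collapse = ", "))
  arm_cols <- paste0("r_", sub("_flexion$", "", dofs), "_m")
  # accept either r_<dof>_m or r_<dof stem>_m column naming
  arm_cols2 <- paste0("r_", dofs, "_m")
  cols <- ifelse(arm_cols %in% names(mus), arm_cols, arm_cols2)
  if (!all(cols %in% names(mus)))
    stop("model schema error: [muscles] missing moment-arm column(s) ",
         paste(setdiff(cols, names(mus)), collapse = ", "))
  muscles <- lapply(seq_len(nrow(mus)), function(i) {
    arms <- as.numeric(mus[i, cols])
    names(arms) <- dofs
    muscle_element(mus$muscle[i], mus$group[i], mus$f_max_N[i], arms)
  })
  seg <- .parse_tsv_block(sec$segments, "segments")
  model_definition(muscles, dofs, seg,
                   check_antagonists = length(muscles) > 2)
}

#' Path of the bundled default model file
#' @return File path string.
#' @export
default_model_path <- function() {
  system.file("extdata", "default_model.tsv", package = "calfcontrib",
              mustWork = TRUE)
}

#' Write a model definition to the text format read by [load_model()]
#' @param model A `model_definition`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path) {
  R <- moment_arm_matrix(model)$values
  lines <- c("# calfcontrib model definition", "[dofs]", model$dofs, "[muscles]",
             paste(c("muscle", "group", "f_max_N",
                     paste0("r_", model$dofs, "_m")), collapse = "\t"))
  for (i in seq_along(model$muscles)) {
    m <- model$muscles[[i]]
    lines <- c(lines, paste(c(m$name, m$group, format(m$f_max),
                              format(R[, i], trim = TRUE)), collapse = "\t"))
  }
  lines <- c(lines, "[segments]",
             paste(names(model$segments), collapse = "\t"))
  for (i in seq_len(nrow(model$segments)))
    lines <- c(lines, paste(unlist(model$segments[i, ]), collapse = "\t"))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}
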