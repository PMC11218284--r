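#' Define a marker gate
#'
#' One phenotype gate: the cell must be positive (score >= the panel's
#' positivity threshold) for every marker in `require_positive` and negative
#' for every marker in `require_negative`; `compartment` optionally restricts
#' the gate to one tissue compartment.
#'
#' @param phenotype phenotype label the gate assigns.
#' @param require_positive,require_negative disjoint marker sets.
#' @param compartment optional `"EPI"` or `"TME"`.
#' @return a list of class `gate_rule`.
#' @export
gate_rule <- function(phenotype, require_positive,
                      require_negative = character(), compartment = NULL) {
  if (length(intersect(require_positive, require_negative)))
    stop("gate '", phenotype, "': a marker cannot be required both positive and negative")
  if (!is.null(compartment)) compartment <- match.arg(compartment, COMPARTMENTS)
  structure(list(phenotype = phenotype,
                 require_positive = as.character(require_positive),
                 require_negative = as.character(require_negative),
                 compartment = compartment),
            class = "gate_rule")
}

#' Define a staining-panel configuration
#'
#' A panel is an ordered marker list plus a priority-ordered list of
#' [gate_rule()]s: each cell is assigned the phenotype of the first gate it
#' satisfies (so gate order is the tie-break for multi-positive cells), or
#' `"UNASSIGNED"` if it satisfies none. `pan_phenotypes` are tallies reported
#' alongside the exclusive phenotypes (e.g. pan-CD3 T cells next to their
#' subsets) and are excluded from the conservation sum of
#' [phenotype_counts()].
#'
#' @param panel_id panel identifier (`"M"`, `"T"`, `"O"`, ...).
#' @param markers ordered character vector of panel markers.
#' @param gates list of [gate_rule()]s in priority order.
#' @param positivity_threshold minimum score counted positive (default 1).
#' @param pan_phenotypes named character vector: tally label -> marker whose
#'   positivity defines the tally.
#' @return a list of class `panel_config`.
#' @export
panel_config <- function(panel_id, markers, gates, positivity_threshold = 1L,
                         pan_phenotypes = character()) {
  stopifnot(length(markers) > 0, positivity_threshold %in% 1:3)
  phens <- vapply(gates, `[[`, "", "phenotype")
  if (anyDuplicated(phens))
    stop("duplicate phenotype name(s) in panel '", panel_id, "': ",
         paste(unique(phens[duplicated(phens)]), collapse = ", "))
  for (g in gates) {
    unknown <- setdiff(c(g$require_positive, g$require_negative), markers)
    if (length(unknown))
      stop("gate '", g$phenotype, "' references marker(s) absent from panel '",
           panel_id, "': ", paste(unknown, collapse = ", "))
  }
  if (length(pan_phenotypes) && !all(pan_phenotypes %in% markers))
    stop("pan phenotype marker(s) absent from panel '", panel_id, "'")
  structure(list(panel_id = panel_id, markers = as.character(markers),
                 gates = gates,
                 positivity_threshold = as.integer(positivity_threshold),
                 pan_phenotypes = pan_phenotypes),
            class = "panel_config")
}

#' The codified default M / T / O panels
#'
#' Encodes the marker combinations of the three staining panels and the
#' negative-screening assignment rules:
#'
#' * **M panel** (myeloid): TAM2 = CD68+IDO1+, TAM1 = CD68+CD163+,
#'   TAM3 = CD68+S100A8+, and `CD68` = cells positive only for CD68.
#'   Multi-positive macrophages are resolved by gate priority
#'   (default TAM2 > TAM1 > TAM3, configurable via `m_priority`).
#' * **T panel**: Treg = CD3+FOXP3+; CD8T = CD3+CD8A+ (FOXP3-);
#'   Tex = CD3+TIM3+ (FOXP3-); CD4Tcon = CD3+ cells double-negative for
#'   CD8A and TIM3 (and FOXP3-) — the residual negative-screening gate.
#'   CD8A+TIM3+ cells fall to CD8T by gate order; pass
#'   `tex_before_cd8t = TRUE` for the alternative reading. CD3T is reported
#'   as the pan-CD3+ tally by default (`cd3t_mode = "pan"`); the literal
#'   "leftover" reading counts CD3+ cells matched by no exclusive gate.
#' * **O panel**: exclusively single-marker-positive cells — B = CD20 only,
#'   Fibroblast = FAP only, MEC = CD34 only, Neutrophil = MPO only; cycling
#'   cancer cells are Ki67-positive cells in the epithelial compartment
#'   (single-positive for Ki67). Multi-positive O-panel cells stay
#'   UNASSIGNED.
#'
#' @param m_priority order of the three double-positive TAM gates.
#' @param tex_before_cd8t resolve CD8A+TIM3+ T cells to Tex instead of CD8T.
#' @param cd3t_mode `"pan"` (all CD3+) or `"leftover"` (CD3+ cells no
#'   exclusive gate matched) for the CD3T tally.
#' @param positivity_threshold minimum score counted positive.
#' @return named list of three [panel_config()]s (`M`, `T`, `O`).
#' @export
default_panels <- function(m_priority = c("TAM2", "TAM1", "TAM3"),
                           tex_before_cd8t = FALSE,
                           cd3t_mode = c("pan", "leftover"),
                           positivity_threshold = 1L) {
  cd3t_mode <- match.arg(cd3t_mode)
  m_priority <- match.arg(m_priority, c("TAM2", "TAM1", "TAM3"),
                          several.ok = TRUE)
  stopifnot(setequal(m_priority, c("TAM1", "TAM2", "TAM3")))
  tam_gates <- list(
    TAM1 = gate_rule("TAM1", c("CD68", "CD163")),
    TAM2 = gate_rule("TAM2", c("CD68", "IDO1")),
    TAM3 = gate_rule("TAM3", c("CD68", "S100A8")))
  m <- panel_config("M", markers = c("CD68", "CD163", "IDO1", "S100A8"),
                    gates = c(unname(tam_gates[m_priority]),
                              list(gate_rule("CD68", "CD68",
                                             c("CD163", "IDO1", "S100A8")))),
                    positivity_threshold = positivity_threshold)
  t_sub <- list(
    gate_rule("Treg", c("CD3", "FOXP3")),
    gate_rule("CD8T", c("CD3", "CD8A"), "FOXP3"),
    gate_rule("Tex", c("CD3", "TIM3"), "FOXP3"))
  if (tex_before_cd8t) t_sub <- t_sub[c(1, 3, 2)]
  t_gates <- c(t_sub,
               list(gate_rule("CD4Tcon", "CD3", c("CD8A", "TIM3", "FOXP3"))))
  t <- panel_config("T", markers = c("CD3", "CD8A", "FOXP3", "TIM3"),
                    gates = t_gates,
                    positivity_threshold = positivity_threshold,
                    pan_phenotypes = c(CD3T = "CD3"))
  attr(t, "cd3t_mode") <- cd3t_mode
  o_markers <- c("CD20", "FAP", "CD34", "MPO", "KI67")
  single <- function(phen, m, compartment = NULL)
    gate_rule(phen, m, setdiff(o_markers, m), compartment)
  o <- panel_config("O", markers = o_markers,
                    gates = list(single("B", "CD20"),
                                 single("Fibroblast", "FAP"),
                                 single("MEC", "CD34"),
                                 single("Neutrophil", "MPO"),
                                 single("CyclingCancer", "KI67", "EPI")),
                    positivity_threshold = positivity_threshold)
  list(M = m, T = t, O = o)
}

#' Marker positivity
#'
#' A cell is positive for a marker iff its 0--3 score is at or above the
#' threshold (default 1: scores 1--3 count positive).
#'
#' @param cells a [cell_table()].
#' @param marker marker name (must be scored on the table).
#' @param threshold minimum positive score.
#' @return logical vector, one element per cell.
#' @export
is_positive <- function(cells, marker, threshold = 1L) {
  if (!marker %in% marker_names(cells))
    stop("marker '", marker, "' is not scored on this cell table")
  s <- cells[[marker]]
  if (anyNA(s)) stop("marker '", marker, "' has unscored cells")
  s >= threshold
}

#' Assign phenotypes by priority-ordered gating
#'
#' Applies the panel's gates in priority order; each cell receives the
#' phenotype of the first gate whose positive/negative marker requirements
#' (and compartment constraint, if any) it satisfies, or `"UNASSIGNED"`.
#' The assignment is deterministic and independent of cell order.
#'
#' @param core a [core_profile()] (or bare [cell_table()]).
#' @param panel a [panel_config()].
#' @return data frame of class `gating_outcome`: `cell_id`, `phenotype`,
#'   `rule` (1-based index of the matched gate, `NA` if unassigned); pan
#'   tallies are attached as attribute `"pan"` (named logical matrix).
#' @export
assign_phenotypes <- function(core, panel) {
  cells <- if (inherits(core, "core_profile")) core$cells else validate_cell_table(core)
  missing <- setdiff(panel$markers, marker_names(cells))
  if (length(missing))
    stop("core is missing score column(s) for panel '", panel$panel_id,
         "': ", paste(missing, collapse = ", "))
  thr <- panel$positivity_threshold
  n <- nrow(cells)
  pos <- vapply(panel$markers, function(m) is_positive(cells, m, thr),
                logical(n))
  if (n == 1L) pos <- matrix(pos, nrow = 1L, dimnames = list(NULL, panel$markers))
  phen <- rep("UNASSIGNED", n)
  rule <- rep(NA_integer_, n)
  open <- rep(TRUE, n)
  for (i in seq_along(panel$gates)) {
    g <- panel$gates[[i]]
    hit <- open
    for (m in g$require_positive) hit <- hit & pos[, m]
    for (m in g$require_negative) hit <- hit & !pos[, m]
    if (!is.null(g$compartment)) hit <- hit & cells$compartment == g$compartment
    phen[hit] <- g$phenotype
    rule[hit] <- i
    open <- open & !hit
  }
  pan <- NULL
  if (length(panel$pan_phenotypes)) {
    mode <- attr(panel, "cd3t_mode")
    pan <- vapply(panel$pan_phenotypes, function(m) {
      p <- pos[, m]
      if (identical(mode, "leftover")) p & is.na(rule) else p
    }, logical(n))
    if (n == 1L)
      pan <- matrix(pan, nrow = 1L, dimnames = list(NULL, names(panel$pan_phenotypes)))
  }
  structure(data.frame(cell_id = cells$cell_id, phenotype = phen, rule = rule,
                       stringsAsFactors = FALSE),
            pan = pan, panel_id = panel$panel_id, class = c("gating_outcome", "data.frame"))
}

#' Phenotype names a panel can emit
#' @param panel a [panel_config()].
#' @param pan include pan tallies.
#' @return character vector.
#' @export
panel_phenotypes <- function(panel, pan = TRUE) {
  out <- vapply(panel$gates, `[[`, "", "phenotype")
  if (pan) out <- c(names(panel$pan_phenotypes), out)
  out
}

#' Per-core phenotype counts by compartment
#'
#' Tabulates assigned phenotypes per tissue compartment. Exclusive phenotype
#' counts plus UNASSIGNED sum to the total cell count (conservation); pan
#' tallies (e.g. CD3T) are reported with `pan = TRUE` and excluded from that
#' sum.
#'
#' @param core a [core_profile()].
#' @param panel a [panel_config()].
#' @param outcomes optional precomputed [assign_phenotypes()] result.
#' @return data frame: `phenotype`, `compartment`, `n`, `pan`.
#' @export
phenotype_counts <- function(core, panel, outcomes = NULL) {
  if (is.null(outcomes)) outcomes <- assign_phenotypes(core, panel)
  cells <- if (inherits(core, "core_profile")) core$cells else core
  stopifnot(nrow(cells) == nrow(outcomes))
  phens <- c(panel_phenotypes(panel, pan = FALSE), "UNASSIGNED")
  grid <- expand.grid(phenotype = phens, compartment = COMPARTMENTS,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  tab <- table(factor(outcomes$phenotype, levels = phens),
               factor(cells$compartment, levels = COMPARTMENTS))
  grid$n <- as.integer(tab[cbind(grid$phenotype, grid$compartment)])
  grid$pan <- FALSE
  pan <- attr(outcomes, "pan")
  if (!is.null(pan)) {
    pan_rows <- do.call(rbind, lapply(colnames(pan), function(p) {
      data.frame(phenotype = p, compartment = COMPARTMENTS,
                 n = as.integer(table(factor(cells$compartment[pan[, p]],
                                             levels = COMPARTMENTS))),
                 pan = TRUE, stringsAsFactors = FALSE)
    }))
    grid <- rbind(pan_rows, grid)
  }
  rownames(grid) <- NULL
  grid
}

#' Gate every core of a cohort and record the assignments
#'
#' Runs [assign_phenotypes()] on each core with its own panel's
#' configuration and writes the resulting labels (including `"UNASSIGNED"`)
#' into the cores' `phenotype` column, as required by the spatial-context
#' functions.
#'
#' @param cores named list of [core_profile()] objects.
#' @param panels named list of [panel_config()]s keyed by panel id.
#' @return the cores, with phenotypes filled in.
#' @export
apply_gating <- function(cores, panels = default_panels()) {
  lapply(cores, function(co) {
    panel <- panels[[co$panel_id]]
    if (is.null(panel)) stop("no panel config for panel id '", co$panel_id, "'")
    out <- assign_phenotypes(co, panel)
    co$cells$phenotype <- out$phenotype
    co
  })
}

#' Read / write a panel configuration as YAML
#'
#' @param path YAML file path.
#' @return a [panel_config()] (read) or `path` invisibly (write).
#' @export
read_panel_config <- function(path) {
  y <- yaml::read_yaml(path)
  gates <- lapply(y$gates, function(g)
    gate_rule(g$phenotype, unlist(g$require_positive),
              if (is.null(g$require_negative)) character() else unlist(g$require_negative),
              g$compartment))
  pan <- if (is.null(y$pan_phenotypes)) character() else unlist(y$pan_phenotypes)
  cfg <- panel_config(y$panel_id, unlist(y$markers), gates,
                      positivity_threshold = y$positivity_threshold %||% 1L,
                      pan_phenotypes = pan)
  if (!is.null(y$cd3t_mode)) attr(cfg, "cd3t_mode") <- y$cd3t_mode
  cfg
}

#' @rdname read_panel_config
#' @param panel a [panel_config()].
#' @export
write_panel_config <- function(panel, path) {
  y <- list(panel_id = panel$panel_id, markers = as.list(panel$markers),
            positivity_threshold = panel$positivity_threshold,
            gates = lapply(panel$gates, function(g)
              Filter(Negate(is.null),
                     list(phenotype = g$phenotype,
                          require_positive = as.list(g$require_positive),
                          require_negative = if (length(g$require_negative))
                            as.list(g$require_negative) else NULL,
                          compartment = g$compartment))))
  if (length(panel$pan_phenotypes))
    y$pan_phenotypes <- as.list(panel$pan_phenotypes)
  if (!is.null(attr(panel, "cd3t_mode"))) y$cd3t_mode <- attr(panel, "cd3t_mode")
  yaml::write_yaml(y, path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
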