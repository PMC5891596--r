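#' Bundle a QM/MM system
#'
#' Convenience container tying together everything the coupling schemes
#' need: full topology and coordinates, region map, link specs, the original
#' MM charge set, an optional QM-derived charge set and the biochemical-unit
#' partition used by the mechanical-embedding charge merge.
#'
#' @param topology full-system [topology()].
#' @param structure n x 3 coordinate matrix (Angstrom).
#' @param region_map [assign_regions()] result.
#' @param link_specs [link_spec()] result.
#' @param mm_charges original MM charges (default: topology charges).
#' @param qm_charges full-length QM-derived charge vector (`NA` outside the
#'   QM region) or `NULL`.
#' @param units biochemical-unit partition per atom (default: residue index).
#' @param external_integer_charge integer charge external to the QM system
#'   (see [merge_charges_me()]).
#' @return an object of class `qmmm_system`.
#' @export
qmmm_system <- function(topology, structure, region_map, link_specs,
                        mm_charges = NULL, qm_charges = NULL, units = NULL,
                        external_integer_charge = 0) {
  structure(list(
    topology = topology, structure = as.matrix(structure),
    region_map = region_map, link_specs = link_specs,
    mm_charges = if (is.null(mm_charges)) topology$atoms$charge else as.numeric(mm_charges),
    qm_charges = qm_charges,
    units = if (is.null(units)) topology$atoms$res_id else units,
    external_integer_charge = external_integer_charge
  ), class = "qmmm_system")
}

## scatter a qm_result gradient (system-1 rows + point-charge rows) onto the
## full-system atoms, with HL chain-rule projection
scatter_qm_gradient <- function(res, sys, placement, point_charges = NULL) {
  g <- project_link_gradient(res$grad_qm, sys$region_map, sys$link_specs,
                             placement, n_atoms(sys$topology))
  if (!is.null(point_charges) && nrow(point_charges) > 0 && !is.null(res$grad_ptch))
    g <- add_rows(g, point_charges$atom, res$grad_ptch)
  g
}

#' Total QM/MM energy and gradient for one coupling scheme
#'
#' Assembles the QM/MM total for the six variants:
#'
#' * `"add"` — additive, electrostatic embedding:
#'   `E = E_QM1+ptch2(HL) + E_MM2-1(CL)`, the MM term cherry-picked by the
#'   rules: bonded terms with at least one MM atom, MM-MM electrostatics,
#'   van der Waals unless both atoms are QM; all MM terms use CL atoms,
#'   coordinates and parameters, never HL.
#' * `"sub"` — subtractive with the van der Waals link-atom correction
#'   (the standard subtractive scheme):
#'   `E = E_QM1+ptch2(HL) + E_MM12,q1=0(CL) - E_MM1,q1=0(HL)`; intra-QM
#'   bonded terms cancel exactly between the two MM calculations, intra-QM
#'   van der Waals pairs involving the link atoms do not — their difference
#'   is the VLAC.
#' * `"sub-strict"` — subtractive with the small-system term evaluated on CL
#'   coordinates and parameters, reproducing the additive result exactly.
#' * `"me"` — mechanical embedding within a subtractive scheme:
#'   `E = E_QM1(HL) + E_MM12(CL) - E_MM1(HL)` with QM-derived charges in the
#'   small-system term and the merged charge set ([merge_charges_me()]) in
#'   the full-system term; with `matched_charges = TRUE` the HL inherits the
#'   CL charge and the full term keeps the original MM charges, making the
#'   QM surrogate and small-system terms cancel exactly.
#' * `"elac"` — electrostatic link-atom correction:
#'   `E = E_QM1+ptch2(HL) + E_MM12(CL) - E_MM1+ptch2(HL)`, QM charges in both
#'   MM terms and the same (unscaled) point-charge model in the small-system
#'   term as in the QM calculation.
#' * `"blac"` — bonded link-atom correction layered on `"sub"`: alternate
#'   bonded parameters for the HL-side (truncated) and optionally CL-side
#'   (full) terms via [apply_blac_parameters()].
#'
#' @param sys a [qmmm_system()].
#' @param scheme one of `"add"`, `"sub"`, `"sub-strict"`, `"me"`, `"elac"`,
#'   `"blac"`.
#' @param backend QM backend (default [surrogate_backend()]).
#' @param matched_charges (ME only) use identical HL/CL charges so the
#'   electrostatics within the QM system cancel exactly.
#' @param blac (BLAC only) list with elements `hl`, `cl` (alternate parameter
#'   tables, see [apply_blac_parameters()]) and `rescale_link_k`.
#' @param gradient assemble the full-system gradient?
#' @return a `qmmm_report`: `total` (kcal/mol), `total_kj`, `terms` (named
#'   top-level decomposition), `mm_components`, `gradient` (n x 3),
#'   `scheme`, `embedding`, `backend`.
#' @export
qmmm_energy <- function(sys, scheme = c("add", "sub", "sub-strict", "me", "elac", "blac"),
                        backend = surrogate_backend(), matched_charges = FALSE,
                        blac = NULL, gradient = TRUE) {
  scheme <- match.arg(scheme)
  rm_ <- sys$region_map
  n <- n_atoms(sys$topology)
  embedding <- if (scheme == "me") "mechanical" else "electrostatic"
  placement <- place_link_atoms(sys$structure, rm_, sys$link_specs)
  grad <- if (gradient) matrix(0, n, 3) else NULL
  mm_comp <- list()

  if (scheme %in% c("add", "sub", "sub-strict", "blac")) {
    trunc <- build_truncated_topology(sys$topology, rm_, sys$link_specs, charges = "zero")
    full_top <- sys$topology
    if (scheme == "blac") {
      if (is.null(blac)) blac <- list()
      mod <- apply_blac_parameters(trunc, full_top,
                                   alt_params_hl = blac$hl %||% list(),
                                   alt_params_cl = blac$cl %||% list(),
                                   link_specs = sys$link_specs,
                                   rescale_link_k = isTRUE(blac$rescale_link_k))
      trunc <- mod$trunc; full_top <- mod$full
    }
    ptch <- build_point_charge_model(sys$topology, sys$structure, rm_, sys$mm_charges)
    qm <- qm_evaluate(trunc, placement$coords,
                      if (nrow(ptch) > 0) ptch else NULL, backend)
    if (gradient) grad <- grad + scatter_qm_gradient(qm, sys, placement, ptch)

    if (scheme == "add") {
      mm <- mm_energy(full_top, sys$structure, term_filter("additive_mm"),
                      charges = sys$mm_charges, region_map = rm_, gradient = gradient)
      if (gradient) grad <- grad + mm$gradient
      terms <- c(qm = qm$energy, mm21 = mm$total)
      mm_comp$mm21 <- mm$components
    } else {
      q0 <- zero_region_charges(sys$mm_charges, rm_, "QM")
      mm12 <- mm_energy(full_top, sys$structure, term_filter("all"),
                        charges = q0, region_map = rm_, gradient = gradient)
      if (gradient) grad <- grad + mm12$gradient
      if (scheme == "sub-strict") {
        mm1 <- mm_energy(sys$topology, sys$structure, term_filter("qm_only"),
                         charges = q0, region_map = rm_, gradient = gradient)
        if (gradient) grad <- grad - mm1$gradient
      } else {
        mm1 <- mm_energy(trunc$topology, placement$coords, term_filter("all"),
                         gradient = gradient)
        if (gradient)
          grad <- grad - project_link_gradient(mm1$gradient, rm_, sys$link_specs,
                                               placement, n)
      }
      terms <- c(qm = qm$energy, mm12 = mm12$total, mm1 = -mm1$total)
      mm_comp$mm12 <- mm12$components
      mm_comp$mm1 <- mm1$components
    }
  } else {                              # me / elac
    if (matched_charges) {
      trunc <- build_truncated_topology(sys$topology, rm_, sys$link_specs,
                                        charges = "keep")
      merged <- sys$mm_charges
    } else {
      if (is.null(sys$qm_charges))
        stop("scheme '", scheme, "' requires a QM-derived charge set (sys$qm_charges)")
      trunc <- build_truncated_topology(sys$topology, rm_, sys$link_specs,
                                        charges = "qm", qm_charges = sys$qm_charges)
      merged <- merge_charges_me(sys$mm_charges, sys$qm_charges, rm_,
                                 unit_partition = sys$units,
                                 external_integer_charge = sys$external_integer_charge)$charges
    }
    ptch <- build_point_charge_model(sys$topology, sys$structure, rm_, sys$mm_charges)
    use_ptch <- scheme == "elac" && nrow(ptch) > 0
    qm <- qm_evaluate(trunc, placement$coords, if (use_ptch) ptch else NULL, backend)
    if (gradient) grad <- grad + scatter_qm_gradient(qm, sys, placement,
                                                     if (use_ptch) ptch else NULL)
    mm12 <- mm_energy(sys$topology, sys$structure, term_filter("all"),
                      charges = merged, region_map = rm_, gradient = gradient)
    if (gradient) grad <- grad + mm12$gradient
    mm1 <- mm_energy(trunc$topology, placement$coords, term_filter("all"),
                     gradient = gradient)
    e_mm1 <- mm1$total
    if (gradient) g_mm1 <- mm1$gradient
    if (use_ptch) {
      emb <- embedding_coulomb(placement$coords, trunc$topology$atoms$charge, ptch)
      e_mm1 <- e_mm1 + emb$energy
      if (gradient) {
        g_mm1 <- g_mm1 + emb$grad_qm
        grad <- add_rows(grad, ptch$atom, -emb$grad_ptch)
      }
    }
    if (gradient)
      grad <- grad - project_link_gradient(g_mm1, rm_, sys$link_specs, placement, n)
    terms <- c(qm = qm$energy, mm12 = mm12$total, mm1 = -e_mm1)
    mm_comp$mm12 <- mm12$components
    mm_comp$mm1 <- mm1$components
  }

  total <- sum(terms)
  structure(list(total = total, total_kj = kcal_to_kj(total), terms = terms,
                 mm_components = mm_comp, gradient = grad, scheme = scheme,
                 embedding = embedding, backend = backend$label),
            class = "qmmm_report")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.qmmm_report <- function(x, ...) {
  cat(sprintf("QM/MM energy [%s, %s embedding, backend %s]\n",
              x$scheme, x$embedding, x$backend))
  cat(sprintf("  total: %.6f kcal/mol (%.6f kJ/mol)\n", x$total, x$total_kj))
  for (nm in names(x$terms)) cat(sprintf("  %-6s %14.6f kcal/mol\n", nm, x$terms[nm]))
  invisible(x)
}

#' Substitute bonded link-atom-correction (BLAC) parameters
#'
#' Replaces bonded parameters keyed by atom-type tuples in the truncated
#' (HL-side) topology and, optionally, the full (CL-side) topology, allowing
#' the HL-side and CL-side terms of the subtractive scheme to be made
#' deliberately different.  Each alternate-parameter entry is a list with a
#' `class` (`"bond"`, `"angle"` or `"dihedral"`), a `types` character vector
#' (matched forward or reversed against the term's atom types) and the new
#' parameter values (`kb`/`r0`, `kth`/`th0`, or `vn2`/`per`/`phase`).  With
#' `rescale_link_k = TRUE` (the *J variants) the Q1-HL force constants are
#' reset afterwards via [scale_link_force_constant()] from the current
#' CL-side Q1-CL bond, cancelling the link-bond contribution between the two
#' MM calculations for every geometry.
#'
#' @param trunc [build_truncated_topology()] result.
#' @param full_topology full-system [topology()].
#' @param alt_params_hl,alt_params_cl lists of alternate-parameter entries
#'   applied to the truncated and full topology respectively (empty lists
#'   leave the topologies unchanged, degenerating BLAC to the standard
#'   subtractive scheme).
#' @param link_specs [link_spec()] (needed for `rescale_link_k`).
#' @param rescale_link_k reset Q1-HL force constants from the CL-side bond?
#' @return list with modified `trunc` and `full` topologies.
#' @export
apply_blac_parameters <- function(trunc, full_topology,
                                  alt_params_hl = list(), alt_params_cl = list(),
                                  link_specs = NULL, rescale_link_k = FALSE) {
  subst <- function(top, entries) {
    for (e in entries) {
      types <- as.character(e$types)
      df_name <- switch(e$class, bond = "bonds", angle = "angles",
                        dihedral = "dihedrals",
                        stop("unknown BLAC term class: ", e$class))
      df <- top[[df_name]]
      cols <- switch(e$class, bond = c("i", "j"), angle = c("i", "j", "k"),
                     dihedral = c("i", "j", "k", "l"))
      tt <- vapply(cols, function(cl) top$atoms$type[df[[cl]]], character(nrow(df)))
      if (nrow(df) == 1) tt <- matrix(tt, nrow = 1)
      fwd <- rep(TRUE, nrow(df)); rev_ <- rep(TRUE, nrow(df))
      for (s in seq_along(cols)) {
        fwd <- fwd & tt[, s] == types[s]
        rev_ <- rev_ & tt[, s] == types[length(types) + 1 - s]
      }
      hit <- which(fwd | rev_)
      if (length(hit) == 0)
        stop("BLAC parameter key not present in topology: ", e$class, " ",
             paste(types, collapse = "-"))
      for (p in intersect(names(e), c("kb", "r0", "kth", "th0", "vn2", "per", "phase")))
        df[[p]][hit] <- e[[p]]
      top[[df_name]] <- df
    }
    top
  }
  trunc$topology <- subst(trunc$topology, alt_params_hl)
  full <- subst(full_topology, alt_params_cl)
  if (rescale_link_k) {
    if (is.null(link_specs)) stop("rescale_link_k requires link_specs")
    for (r in seq_len(nrow(link_specs))) {
      ## current CL-side parameters (possibly just substituted)
      q1 <- link_specs$q1[r]; cl <- link_specs$cl[r]
      bf <- full$bonds
      hit_f <- which((bf$i == q1 & bf$j == cl) | (bf$j == q1 & bf$i == cl))
      bt <- trunc$topology$bonds
      q1t <- match(q1, trunc$map); hlt <- trunc$hl_rows[r]
      hit_t <- which((bt$i == q1t & bt$j == hlt) | (bt$j == q1t & bt$i == hlt))
      bt$kb[hit_t] <- scale_link_force_constant(bf$kb[hit_f], bf$r0[hit_f],
                                                bt$r0[hit_t])
      trunc$topology$bonds <- bt
    }
  }
  list(trunc = trunc, full = full)
}

#' Tabulate a scheme report's energy decomposition
#'
#' Renders the top-level term breakdown (two terms for the additive scheme,
#' three for the subtractive family) together with the per-class MM
#' decomposition, re-checking that the terms sum to the reported total.
#'
#' @param report a `qmmm_report` from [qmmm_energy()].
#' @return data frame with columns `term`, `class`, `kcal_mol`, `kj_mol`.
#' @export
scheme_decomposition <- function(report) {
  stopifnot(inherits(report, "qmmm_report"))
  if (abs(sum(report$terms) - report$total) > 1e-10 * max(1, abs(report$total)))
    stop("internal inconsistency: terms do not sum to total")
  rows <- data.frame(term = names(report$terms), class = "total",
                     kcal_mol = as.numeric(report$terms))
  for (nm in names(report$mm_components)) {
    comp <- report$mm_components[[nm]]
    sgn <- if (nm == "mm1") -1 else 1
    rows <- rbind(rows, data.frame(term = nm, class = names(comp),
                                   kcal_mol = sgn * as.numeric(comp)))
  }
  rows$kj_mol <- kcal_to_kj(rows$kcal_mol)
  rows
}
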