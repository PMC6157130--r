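# The a priori locus model: a recursive (acyclic) system of linear equations
# over observed variables. Endogenous: TG1..TG4, HDL1..HDL4 and one variable
# per CpG; exogenous: SNP dosage plus covariates.

#' Locus configuration
#'
#' Describes one tag SNP: identity, genomic position, alleles, effect-allele
#' frequency, the expected direction of its TG effect from prior GWAS (+1 or
#' -1, used for the directional-consistency filter), and the CpG ids modeled
#' at the locus.
#'
#' @param rsid,chrom,pos SNP identity and 1-based position.
#' @param effect_allele,other_allele allele labels.
#' @param eaf effect-allele frequency in `[0,1]`.
#' @param expected_tg_direction `+1` or `-1`.
#' @param cpg_ids character vector of CpG ids (may be empty).
#' @return an object of class `locus_config`.
#' @export
locus_config <- function(rsid, chrom, pos, effect_allele = "A",
                         other_allele = "B", eaf = 0.5,
                         expected_tg_direction = 1, cpg_ids = character(0)) {
  check_prob(eaf, "eaf")
  if (!expected_tg_direction %in% c(-1, 1))
    stop_bad_arg("expected_tg_direction must be +1 or -1")
  if (anyDuplicated(cpg_ids)) stop_bad_arg("cpg_ids must be distinct")
  structure(list(rsid = rsid, chrom = as.character(chrom),
                 pos = as.integer(pos),
                 effect_allele = effect_allele, other_allele = other_allele,
                 eaf = eaf,
                 expected_tg_direction = as.integer(expected_tg_direction),
                 cpg_ids = as.character(cpg_ids)),
            class = "locus_config")
}

#' Build the a priori locus path model
#'
#' Constructs the default model structure:
#' \itemize{
#'   \item lag effects `TG[t-1] -> TG[t]` and `HDL[t-1] -> HDL[t]` (t = 2..4);
#'   \item contemporaneous `HDL[t] -> TG[t]` (t = 1..4);
#'   \item `SNP -> TG[t]` and `SNP -> HDL[t]` for every visit;
#'   \item `SNP -> CpG` and `CpG -> TG2` for each CpG (methylation was
#'     measured at visit 2, so CpGs act only on visit-2 TG);
#'   \item every covariate on every TG and HDL visit.
#' }
#' Covariates deliberately do not point at CpGs: methylation confounding is
#' handled upstream by PC residualisation. Overrides may add or remove edges,
#' subject to the endogenous subgraph remaining acyclic.
#'
#' @param locus a [locus_config()] object (or a single row of [goldn_loci()]).
#' @param covariates non-empty character vector of covariate names.
#' @param overrides optional list with elements `add` and/or `remove`, each a
#'   data.frame with columns `from`, `to`.
#' @return an object of class `path_model`: list with `endogenous`,
#'   `exogenous`, `edges` (data.frame from, to), `cpg_ids`, `locus`.
#' @examples
#' m <- path_model(locus_config("rs1748195", 1, 63049593,
#'                              cpg_ids = "cg00161770"))
#' length(m$endogenous)  # 9 = 8 lipid visits + 1 CpG
#' @export
path_model <- function(locus,
                       covariates = c("sex", "age", "center", "smoking"),
                       overrides = NULL) {
  if (inherits(locus, "data.frame")) {
    stopifnot(nrow(locus) == 1L)
    cpgs <- trimws(strsplit(locus$cpgs_included, ",", fixed = TRUE)[[1L]])
    locus <- locus_config(locus$rsid, locus$chrom, locus$pos,
                          locus$effect_allele, locus$other_allele, locus$eaf,
                          locus$expected_tg_direction, cpgs)
  }
  if (!inherits(locus, "locus_config"))
    stop_bad_arg("locus must be a locus_config or a goldn_loci() row")
  if (length(covariates) == 0L) stop_bad_arg("covariates must be non-empty")
  tg <- paste0("TG", 1:4); hdl <- paste0("HDL", 1:4)
  cpgs <- locus$cpg_ids
  endogenous <- c(tg, hdl, cpgs)
  exogenous <- c("SNP", covariates)
  if (anyDuplicated(c(endogenous, exogenous)))
    stop_bad_arg("variable names collide")

  e <- rbind(
    data.frame(from = tg[1:3], to = tg[2:4]),
    data.frame(from = hdl[1:3], to = hdl[2:4]),
    data.frame(from = hdl, to = tg),
    data.frame(from = "SNP", to = c(tg, hdl)),
    if (length(cpgs)) data.frame(from = c(rep("SNP", length(cpgs)), cpgs),
                                 to = c(cpgs, rep("TG2", length(cpgs)))),
    data.frame(from = rep(covariates, each = 8L),
               to = rep(c(tg, hdl), length(covariates))))
  rownames(e) <- NULL

  if (!is.null(overrides)) {
    if (!is.null(overrides$remove)) {
      e <- e[is.na(match(paste(e$from, e$to),
                         paste(overrides$remove$from, overrides$remove$to))), ,
             drop = FALSE]
    }
    if (!is.null(overrides$add)) {
      e <- rbind(e, overrides$add[, c("from", "to")])
      e <- unique(e)
    }
  }

  new_path_model(endogenous, exogenous, e, locus = locus, cpg_ids = cpgs)
}

#' Construct a path model from an explicit variable and edge list
#'
#' Low-level constructor behind [path_model()], useful for arbitrary recursive
#' systems (simulation studies, oracles). Validates that every edge ends at an
#' endogenous variable and that the endogenous subgraph is acyclic.
#'
#' @param endogenous,exogenous variable names (disjoint).
#' @param edges data.frame with columns `from`, `to`.
#' @param locus optional [locus_config()] carried for reporting.
#' @param cpg_ids CpG subset of `endogenous` (default none).
#' @return a `path_model` object.
#' @export
new_path_model <- function(endogenous, exogenous, edges,
                           locus = locus_config("custom", "0", 1L),
                           cpg_ids = character(0)) {
  e <- as.data.frame(edges)[, c("from", "to")]
  rownames(e) <- NULL
  if (anyDuplicated(c(endogenous, exogenous)))
    stop_bad_arg("variable names collide")
  bad <- !(e$from %in% c(endogenous, exogenous)) | !(e$to %in% endogenous)
  if (any(bad))
    stop_bad_arg("invalid edge(s): ",
                 paste(e$from[bad], "->", e$to[bad], collapse = ", "),
                 " (edges must end at an endogenous variable)")
  if (anyDuplicated(paste(e$from, e$to)))
    stop_bad_arg("duplicate edges")
  model <- structure(list(endogenous = endogenous, exogenous = exogenous,
                          edges = e, cpg_ids = cpg_ids, locus = locus),
                     class = "path_model")
  model$topo_order <- endo_topo_order(model)  # errors on a cycle
  model
}

# topological order of the endogenous subgraph; error if cyclic
endo_topo_order <- function(model) {
  ee <- model$edges[model$edges$from %in% model$endogenous, , drop = FALSE]
  g <- igraph::graph_from_data_frame(
    ee, directed = TRUE,
    vertices = data.frame(name = model$endogenous))
  if (!igraph::is_dag(g))
    stop_bad_arg("model construction error: the endogenous subgraph is cyclic")
  names(igraph::topo_sort(g, mode = "out"))
}

#' Parents of a variable in a path model
#' @param model a [path_model()].
#' @param var variable name.
#' @return character vector of direct parents.
#' @export
model_parents <- function(model, var) {
  if (!var %in% c(model$endogenous, model$exogenous))
    stop_bad_arg("unknown variable: ", var)
  model$edges$from[model$edges$to == var]
}

#' Enumerate simple directed paths
#'
#' All simple directed paths from `source` to `sink`, in deterministic
#' (lexicographic by variable sequence) order.
#'
#' @param model a [path_model()].
#' @param source,sink variable names.
#' @return list of character vectors (ordered variable chains); empty list if
#'   the sink is unreachable.
#' @export
enumerate_paths <- function(model, source = "SNP", sink = "TG4") {
  vars <- c(model$endogenous, model$exogenous)
  if (!source %in% vars) stop_bad_arg("unknown variable: ", source)
  if (!sink %in% vars) stop_bad_arg("unknown variable: ", sink)
  g <- igraph::graph_from_data_frame(model$edges, directed = TRUE,
                                     vertices = data.frame(name = vars))
  if (igraph::degree(g, source, mode = "out") == 0L) return(list())
  ps <- igraph::all_simple_paths(g, from = source, to = sink, mode = "out")
  chains <- lapply(ps, function(p) names(igraph::V(g))[as.integer(p)])
  key <- vapply(chains, paste, "", collapse = "\r")
  chains[order(key)]
}

#' Render a pathway chain as a report string
#' @param chain character vector of variable names.
#' @return single string, variables joined by arrows.
#' @export
format_chain <- function(chain) paste(chain, collapse = " \u2192 ")

#' Count free parameters of a path model
#'
#' One coefficient per edge, plus an intercept and a residual variance per
#' endogenous variable (this package's counting convention; software packages
#' differ in whether exogenous moments are counted).
#'
#' @param model a [path_model()].
#' @return integer count.
#' @export
count_free_parameters <- function(model) {
  nrow(model$edges) + 2L * length(model$endogenous)
}

#' @export
print.path_model <- function(x, ...) {
  cat(sprintf("Locus path model: %s (%d endogenous, %d exogenous, %d edges, %d free parameters)\n",
              x$locus$rsid, length(x$endogenous), length(x$exogenous),
              nrow(x$edges), count_free_parameters(x)))
  # static text rendering of the DAG, one endogenous equation per line
  for (v in x$topo_order) {
    pa <- model_parents(x, v)
    cat(sprintf("  %s <- %s\n", v,
                if (length(pa)) paste(pa, collapse = " + ") else "(intercept only)"))
  }
  invisible(x)
}

#' Serialize a path model to a structured text file
#' @param model a [path_model()].
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_path_model <- function(model, path) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c(paste("locus:", model$locus$rsid),
               paste("endogenous:", paste(model$endogenous, collapse = ",")),
               paste("exogenous:", paste(model$exogenous, collapse = ",")),
               paste("free_parameters:", count_free_parameters(model)),
               "edges:",
               paste0("  ", model$edges$from, " -> ", model$edges$to)), con)
  invisible(path)
}
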