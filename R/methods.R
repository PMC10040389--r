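#' @include AllGenerics.R
NULL

# ---- PathwayDB ----

#' @describeIn pathwayIds pathway ids
#' @export
setMethod("pathwayIds", "PathwayDB", function(x) names(x@geneSets))

#' @describeIn geneSets gene sets
#' @export
setMethod("geneSets", "PathwayDB", function(x) x@geneSets)

#' @describeIn geneSigns per-gene direction signs
#' @export
setMethod("geneSigns", "PathwayDB", function(x) x@signs)

#' @describeIn geneUniverse all genes across pathways
#' @export
setMethod("geneUniverse", "PathwayDB", function(x)
  sort(unique(unlist(x@geneSets, use.names = FALSE))))

setMethod("show", "PathwayDB", function(object) {
  cat("PathwayDB [", ifelse(is.na(object@source), "unnamed", object@source),
      "]: ", length(object@geneSets), " pathways, ",
      length(geneUniverse(object)), " genes",
      if (any(lengths(object@signs) > 0)) ", signed" else "", "\n", sep = "")
})

#' Construct a PathwayDB
#'
#' @param geneSets named list of character gene vectors.
#' @param signs optional named list of named +/-1 vectors per pathway.
#' @param source collection tag.
#' @return a \linkS4class{PathwayDB}.
#' @export
PathwayDB <- function(geneSets, signs = NULL, source = NA_character_) {
  if (is.null(signs)) signs <- rep(list(numeric()), length(geneSets))
  if (is.null(names(signs)) && length(signs)) names(signs) <- names(geneSets)
  signs <- signs[names(geneSets)]
  signs[vapply(signs, is.null, logical(1))] <- list(numeric())
  names(signs) <- names(geneSets)
  new("PathwayDB", geneSets = geneSets, signs = signs, source = source)
}

# ---- LigandTargetPrior ----

#' @describeIn ligands ligand ids
#' @export
setMethod("ligands", "LigandTargetPrior", function(x) rownames(x@potential))

#' @describeIn ligandInfo annotation table
#' @export
setMethod("ligandInfo", "LigandTargetPrior", function(x) x@annotation)

#' @describeIn potentials weight matrix
#' @export
setMethod("potentials", "LigandTargetPrior", function(x) x@potential)

#' @describeIn geneUniverse genes in the prior's target space
#' @export
setMethod("geneUniverse", "LigandTargetPrior", function(x) colnames(x@potential))

setMethod("show", "LigandTargetPrior", function(object) {
  n_sec <- sum(object@annotation$location == "extracellular space")
  cat("LigandTargetPrior: ", nrow(object@potential), " ligands (",
      n_sec, " extracellular) x ", ncol(object@potential), " genes, ",
      sum(object@potential > 0), " positive links\n", sep = "")
})

#' Construct a LigandTargetPrior
#'
#' @param potential ligand x gene nonnegative weight matrix with dimnames.
#' @param location named character per ligand: "extracellular space"/"other".
#' @param molecule_class named character per ligand.
#' @return a \linkS4class{LigandTargetPrior}.
#' @export
LigandTargetPrior <- function(potential, location, molecule_class) {
  lig <- rownames(potential)
  ann <- S4Vectors::DataFrame(
    location = unname(location[lig]),
    molecule_class = unname(molecule_class[lig]),
    row.names = lig
  )
  new("LigandTargetPrior", potential = potential, annotation = ann)
}

#' Positive-weight target genes of one ligand
#'
#' @param prior a \linkS4class{LigandTargetPrior}.
#' @param ligand ligand id.
#' @return named numeric vector of positive weights, names = genes.
#' @export
ligandWeights <- function(prior, ligand) {
  if (!ligand %in% ligands(prior))
    stop("unknown ligand: ", ligand)
  w <- potentials(prior)[ligand, ]
  w <- as.numeric(w)
  names(w) <- colnames(potentials(prior))
  w[w > 0]
}

# ---- MCDMGraph ----

#' @describeIn mcdmEdges edge table
#' @export
setMethod("mcdmEdges", "MCDMGraph", function(x) x@edges)

#' @describeIn mcdmNodes node table
#' @export
setMethod("mcdmNodes", "MCDMGraph", function(x) x@nodes)

setMethod("show", "MCDMGraph", function(object) {
  cat(if (isTRUE(object@multiOrgan)) "MO-MCDM" else "MCDM",
      ": ", nrow(object@nodes), " (organ, cell type) nodes, ",
      nrow(object@edges), " UR edges (",
      length(unique(object@edges$ligand)), " distinct URs)\n", sep = "")
})

#' Construct an MCDMGraph
#'
#' @param nodes data.frame/DataFrame with organ, cell_type, n_cells.
#' @param edges data.frame/DataFrame with sender_organ, sender_cell, ligand,
#'   receiver_organ, receiver_cell, pcc and list column targets.
#' @param multiOrgan logical.
#' @return an \linkS4class{MCDMGraph}.
#' @export
MCDMGraph <- function(nodes, edges, multiOrgan = FALSE) {
  new("MCDMGraph",
      nodes = S4Vectors::DataFrame(nodes),
      edges = S4Vectors::DataFrame(edges),
      multiOrgan = multiOrgan)
}

# ---- ProgramTree ----

#' @describeIn programs program assignment
#' @export
setMethod("programs", "ProgramTree", function(x) x@programs)

#' @describeIn subprograms subprogram assignment
#' @export
setMethod("subprograms", "ProgramTree", function(x) x@subprograms)

setMethod("show", "ProgramTree", function(object) {
  cat("ProgramTree: ", nrow(object@dist), " pathways",
      if (length(object@programs))
        paste0(", ", length(unique(object@programs)), " programs"),
      if (length(object@subprograms))
        paste0(", ", length(unique(object@subprograms)), " subprograms"),
      "\n", sep = "")
})

# ---- SyntheticTruth ----

#' @describeIn urActivity planted activity map
#' @export
setMethod("urActivity", "SyntheticTruth", function(x) x@urActivity)

#' @describeIn urActivity-set replace the activity map
#' @export
setMethod("urActivity<-", "SyntheticTruth", function(x, value) {
  x@urActivity <- as.data.frame(value)
  validObject(x)
  x
})

#' @describeIn urTargets planted target sets
#' @export
setMethod("urTargets", "SyntheticTruth", function(x) x@urTargets)

#' @describeIn cellLabels planted cell labels
#' @export
setMethod("cellLabels", "SyntheticTruth", function(x) x@cellLabels)

setMethod("show", "SyntheticTruth", function(object) {
  cat("SyntheticTruth: ", length(object@programOf), " pathways / ",
      length(unique(object@programOf)), " programs; ",
      length(object@urTargets), " URs (",
      nrow(object@urActivity), " activity entries); ",
      length(object@cellLabels), " labeled cells; takeover UR: ",
      ifelse(is.na(object@takeoverUR), "none", object@takeoverUR),
      "; seed ", object@seed, "\n", sep = "")
})
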