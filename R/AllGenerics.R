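#' @include AllClasses.R
NULL

#' Pathway ids of a PathwayDB
#' @param x a \linkS4class{PathwayDB}.
#' @return character vector of pathway ids.
#' @export
setGeneric("pathwayIds", function(x) standardGeneric("pathwayIds"))

#' Gene sets of a PathwayDB
#' @param x a \linkS4class{PathwayDB}.
#' @return named list of character vectors.
#' @export
setGeneric("geneSets", function(x) standardGeneric("geneSets"))

#' Per-gene activation-direction signs of a PathwayDB
#' @param x a \linkS4class{PathwayDB}.
#' @return named list of named +/-1 vectors (empty when unsigned).
#' @export
setGeneric("geneSigns", function(x) standardGeneric("geneSigns"))

#' Union of all genes in a collection
#' @param x a \linkS4class{PathwayDB} or \linkS4class{LigandTargetPrior}.
#' @return character vector of gene ids.
#' @export
setGeneric("geneUniverse", function(x) standardGeneric("geneUniverse"))

#' Ligand (UR) ids of a prior
#' @param x a \linkS4class{LigandTargetPrior}.
#' @return character vector.
#' @export
setGeneric("ligands", function(x) standardGeneric("ligands"))

#' Ligand annotation table of a prior
#' @param x a \linkS4class{LigandTargetPrior}.
#' @return \code{DataFrame} with columns location, molecule_class.
#' @export
setGeneric("ligandInfo", function(x) standardGeneric("ligandInfo"))

#' Regulatory-potential matrix of a prior
#' @param x a \linkS4class{LigandTargetPrior}.
#' @return ligand x gene weight matrix.
#' @export
setGeneric("potentials", function(x) standardGeneric("potentials"))

#' Edge table of an MCDM graph
#' @param x an \linkS4class{MCDMGraph}.
#' @return \code{DataFrame} of edges (list column \code{targets}).
#' @export
setGeneric("mcdmEdges", function(x) standardGeneric("mcdmEdges"))

#' Node table of an MCDM graph
#' @param x an \linkS4class{MCDMGraph}.
#' @return \code{DataFrame} of (organ, cell_type, n_cells) nodes.
#' @export
setGeneric("mcdmNodes", function(x) standardGeneric("mcdmNodes"))

#' Program assignment of a ProgramTree
#' @param x a \linkS4class{ProgramTree}.
#' @return named character vector pathway -> program label.
#' @export
setGeneric("programs", function(x) standardGeneric("programs"))

#' Subprogram assignment of a ProgramTree
#' @param x a \linkS4class{ProgramTree}.
#' @return named character vector pathway -> subprogram label.
#' @export
setGeneric("subprograms", function(x) standardGeneric("subprograms"))

#' Planted UR activity of a SyntheticTruth
#' @param x a \linkS4class{SyntheticTruth}.
#' @return data.frame (group, ur, direction).
#' @export
setGeneric("urActivity", function(x) standardGeneric("urActivity"))

#' Set the planted UR activity map
#' @param x a \linkS4class{SyntheticTruth}.
#' @param value data.frame with columns group, ur, direction (+1/-1/0).
#' @return the modified object.
#' @export
setGeneric("urActivity<-", function(x, value) standardGeneric("urActivity<-"))

#' Planted UR target sets
#' @param x a \linkS4class{SyntheticTruth}.
#' @return named list UR -> gene set.
#' @export
setGeneric("urTargets", function(x) standardGeneric("urTargets"))

#' Planted cell-type labels
#' @param x a \linkS4class{SyntheticTruth}.
#' @return named character cell id -> type.
#' @export
setGeneric("cellLabels", function(x) standardGeneric("cellLabels"))
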