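#' @import methods
#' @importFrom S4Vectors DataFrame
NULL

#' PathwayDB: a collection of pathway gene sets
#'
#' Container for pathway gene sets (as read from GMT files), optionally
#' carrying per-gene activation-direction signs (+1 = the gene goes up when
#' the pathway is activated, -1 = down), in the signed-GMT dialect
#' \code{SYMBOL:+1} / \code{SYMBOL:-1}.
#'
#' @slot geneSets named list of character vectors, one per pathway.
#' @slot signs named list; per pathway a named numeric vector of +/-1 over
#'   (a subset of) its member genes, or an empty vector when unsigned.
#' @slot source single character tag naming the collection.
#'
#' @export
setClass("PathwayDB",
  representation(geneSets = "list", signs = "list", source = "character"),
  prototype(geneSets = list(), signs = list(), source = NA_character_)
)

setValidity("PathwayDB", function(object) {
  gs <- object@geneSets
  if (length(gs) == 0L) return(TRUE)
  if (is.null(names(gs)) || anyDuplicated(names(gs)))
    return("pathway ids must be unique and named")
  if (any(lengths(gs) == 0L))
    return("pathway gene sets must be nonempty")
  sg <- object@signs
  if (length(sg) != length(gs))
    return("signs must have one entry per pathway (possibly empty)")
  for (i in seq_along(sg)) {
    s <- sg[[i]]
    if (length(s) == 0L) next
    if (!all(names(s) %in% gs[[i]]))
      return(sprintf("signs of pathway '%s' include non-member genes", names(gs)[i]))
    if (!all(s %in% c(-1, 1)))
      return("direction signs must be +1 or -1")
  }
  TRUE
})

#' LigandTargetPrior: weighted ligand-to-target regulatory potential
#'
#' The prior knowledge linking each ligand (upstream regulator, UR) to the
#' genes it can regulate, with nonnegative regulatory-potential weights, plus
#' per-ligand annotations: cellular location (\code{"extracellular space"}
#' for secreted URs, \code{"other"} otherwise) and molecule class.
#'
#' @slot potential ligand x gene matrix of nonnegative weights
#'   (\code{Matrix::dgCMatrix} or base matrix).
#' @slot annotation \code{DataFrame} with rownames = ligand ids and columns
#'   \code{location}, \code{molecule_class}.
#'
#' @export
setClass("LigandTargetPrior",
  representation(potential = "ANY", annotation = "DataFrame")
)

setValidity("LigandTargetPrior", function(object) {
  pot <- object@potential
  if (is.null(rownames(pot)) || is.null(colnames(pot)))
    return("potential matrix must have ligand rownames and gene colnames")
  if (any(pot < 0)) return("regulatory-potential weights must be nonnegative")
  if (any(Matrix::rowSums(pot > 0) == 0))
    return("every ligand needs at least one positive-weight target gene")
  ann <- object@annotation
  if (!identical(rownames(ann), rownames(pot)))
    return("annotation rownames must match potential rownames")
  if (!all(c("location", "molecule_class") %in% colnames(ann)))
    return("annotation needs 'location' and 'molecule_class' columns")
  TRUE
})

#' MCDMGraph: a multicellular disease model
#'
#' Directed multigraph with (organ, cell type) nodes and UR-mediated edges.
#' Parallel edges between the same node pair are allowed and differ by ligand.
#' Each edge carries the ligand (UR), the inferred downstream target genes in
#' the receiver, and the ligand-activity score (Pearson correlation of the
#' ligand's regulatory potential with receiver DEG membership; edges require
#' activity > 0).
#'
#' @slot nodes \code{DataFrame}: organ, cell_type, n_cells.
#' @slot edges \code{DataFrame}: sender_organ, sender_cell, ligand,
#'   receiver_organ, receiver_cell, pcc, and a list column \code{targets}.
#' @slot multiOrgan logical; TRUE for a multi-organ MCDM (cross-organ,
#'   secreted-UR-only edges).
#'
#' @export
setClass("MCDMGraph",
  representation(nodes = "DataFrame", edges = "DataFrame", multiOrgan = "logical"),
  prototype(multiOrgan = FALSE)
)

setValidity("MCDMGraph", function(object) {
  ed <- object@edges
  need <- c("sender_organ", "sender_cell", "ligand",
            "receiver_organ", "receiver_cell", "pcc", "targets")
  if (nrow(ed) > 0 && !all(need %in% colnames(ed)))
    return(paste("edges must have columns:", paste(need, collapse = ", ")))
  if (nrow(ed) > 0 && any(ed$pcc <= 0))
    return("edge activity (pcc) must be > 0")
  nd <- object@nodes
  if (nrow(nd) > 0 && any(nd$n_cells < 0, na.rm = TRUE))
    return("node cell counts must be >= 0")
  if (isTRUE(object@multiOrgan) && nrow(ed) > 0 &&
      any(ed$sender_organ == ed$receiver_organ))
    return("a multi-organ MCDM cannot contain within-organ edges")
  TRUE
})

#' ProgramTree: pathway dendrogram with program/subprogram assignments
#'
#' Result of connective pathway analysis: Ward (ward.D2) hierarchical
#' clustering of pathways on 1-Jaccard distances between their DEG-restricted
#' gene sets, with a top-level cut into programs and per-program cuts into
#' subprograms.
#'
#' @slot hclust the \code{stats::hclust} merge tree.
#' @slot dist symmetric 1-Jaccard distance matrix over pathways.
#' @slot programs named character: pathway id -> program label (e.g. "P1").
#' @slot subprograms named character: pathway id -> subprogram label
#'   (e.g. "SP1.2"); empty until \code{cutPrograms()} is called with k_sub.
#'
#' @export
setClass("ProgramTree",
  representation(hclust = "ANY", dist = "matrix",
                 programs = "character", subprograms = "character"),
  prototype(programs = character(), subprograms = character())
)

setValidity("ProgramTree", function(object) {
  d <- object@dist
  if (!isSymmetric(unname(d))) return("distance matrix must be symmetric")
  if (any(d < -1e-12) || any(d > 1 + 1e-12))
    return("1-Jaccard distances must lie in [0, 1]")
  if (any(abs(diag(d)) > 1e-12)) return("distance diagonal must be zero")
  if (length(object@programs) &&
      !all(names(object@programs) %in% rownames(d)))
    return("program assignments must cover tree leaves only")
  TRUE
})

#' SyntheticTruth: planted ground truth for the synthetic pipeline
#'
#' Records everything the synthetic generators planted, so downstream results
#' can be scored against known truth: the pathway -> program map, per-gene
#' activation-direction signs, the (group, UR) activity map, UR target sets,
#' cell-type labels, and the planted takeover UR.
#'
#' @slot programOf named character: pathway id -> program label.
#' @slot geneSigns named numeric: gene -> +/-1 annotated activation direction.
#' @slot urActivity data.frame with columns group, ur, direction (+1/-1/0).
#' @slot urTargets named list: UR id -> target gene set.
#' @slot cellLabels named character: cell id -> true cell type.
#' @slot takeoverUR single character (NA when no takeover UR planted).
#' @slot seed integer seed that reproduces the generated artifacts.
#'
#' @export
setClass("SyntheticTruth",
  representation(programOf = "character", geneSigns = "numeric",
                 urActivity = "data.frame", urTargets = "list",
                 cellLabels = "character", takeoverUR = "character",
                 seed = "integer"),
  prototype(programOf = character(), geneSigns = numeric(),
            urActivity = data.frame(group = character(), ur = character(),
                                    direction = numeric()),
            urTargets = list(), cellLabels = character(),
            takeoverUR = NA_character_, seed = NA_integer_)
)

setValidity("SyntheticTruth", function(object) {
  ua <- object@urActivity
  if (!all(c("group", "ur", "direction") %in% colnames(ua)))
    return("urActivity needs columns group, ur, direction")
  if (nrow(ua) && !all(ua$direction %in% c(-1, 0, 1)))
    return("ur directions must be -1, 0 or +1")
  if (length(object@geneSigns) && !all(object@geneSigns %in% c(-1, 1)))
    return("gene signs must be +1 or -1")
  TRUE
})
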