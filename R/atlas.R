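# Packaged 68-node functional atlas metadata: node order, names,
# abbreviations, and both the consensus-clustering and final (ICN-informed)
# module assignments. The final assignment overrides the clustering result
# for three discrepant lateral DMN nodes so that nodes derived from the same
# intrinsic connectivity network share a module.

#' The 68-node functional atlas
#'
#' @return data frame with columns `module_name` (SSM, TIL, TPN, TNN, VIS),
#'   `node_number` (matrix order 1..68), `name`, `abbreviation`,
#'   `final_assignment` (1..5) and `clustering_assignment` (1..5).
#' @export
node_atlas <- function() {
  path <- system.file("extdata", "node_atlas.tsv", package = "dynmod")
  if (path == "") stop("node_atlas.tsv not found in installed package")
  atlas <- utils::read.table(path, header = TRUE, sep = "\t",
                             stringsAsFactors = FALSE, quote = "")
  stopifnot(nrow(atlas) == 68)
  atlas
}

#' Fixed final module assignment (5 modules over 68 nodes)
#'
#' @return integer vector of length 68: the final module label of each node
#'   in matrix order.
#' @export
final_partition <- function() {
  node_atlas()$final_assignment
}

#' Default-mode sub-network definitions
#'
#' The four DMN sub-networks inside the task-negative module, four nodes
#' each: pDMN (nodes 42-45), dDMN (46-49), vDMN (50-53), aDMN (54-57).
#'
#' @return named list of `list(name, node_ids)`.
#' @export
dmn_subnetworks <- function() {
  defs <- list(
    pDMN = list(name = "pDMN", node_ids = 42:45),
    dDMN = list(name = "dDMN", node_ids = 46:49),
    vDMN = list(name = "vDMN", node_ids = 50:53),
    aDMN = list(name = "aDMN", node_ids = 54:57)
  )
  defs
}
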