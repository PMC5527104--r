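#' Patristic distance matrix from a Newick guide tree
#'
#' Reads a Newick tree with branch lengths and returns the matrix of
#' patristic distances (sum of branch lengths along the path connecting two
#' leaves), the input to the Gene Relatedness test.
#'
#' @param path path to a Newick file.
#' @return symmetric numeric matrix with leaf labels as dimnames; zero
#'   diagonal.
#' @examples
#' nwk <- tempfile(fileext = ".nwk")
#' writeLines("((A:1,B:1):1,C:2);", nwk)
#' read_newick_distances(nwk)["A", "C"]  # 4
#' @export
read_newick_distances <- function(path) {
  tr <- tryCatch(ape::read.tree(path),
                 error = function(e) stop("cannot parse Newick: ",
                                          conditionMessage(e)))
  if (is.null(tr)) stop("cannot parse Newick file: ", path)
  if (is.null(tr$edge.length) || anyNA(tr$edge.length))
    stop("Newick tree lacks branch lengths; patristic distances undefined")
  d <- ape::cophenetic.phylo(tr)
  d[order(rownames(d)), order(colnames(d)), drop = FALSE]
}
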