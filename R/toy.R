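#' Toy 22-node worked example (synthetic fixture)
#'
#' A small hand-built instance used throughout the documentation and tests to
#' illustrate how the two ranking schemes differ. It is a synthetic stand-in
#' constructed to exhibit the canonical failure mode of descending-order
#' ranking: 22 nodes in three communities of sizes 9 > 7 > 6, where the three
#' highest-degree nodes (1, 4, 5) all sit in the largest community C1, and
#' the three highest-betweenness nodes (13, 14, 15) all sit in C2. The
#' community-aware scheme instead picks the per-community leaders: nodes
#' 5, 13, 19 by degree and nodes 3, 13, 21 by betweenness.
#'
#' @return A list with `degree` and `betweenness` (both
#'   `"centrality_scores"`) and `partition` (a [partition] with communities
#'   `C1`, `C2`, `C3`).
#' @examples
#' toy <- toy_example()
#' community_aware_rank(toy$degree, toy$partition, budget = 3)
#' @export
toy_example <- function() {
  deg <- c("1" = 7, "2" = 4, "3" = 5, "4" = 7, "5" = 8,
           "6" = 4, "7" = 3, "8" = 3, "9" = 2,
           "10" = 4, "11" = 3, "12" = 3, "13" = 6, "14" = 5,
           "15" = 5, "16" = 2,
           "17" = 3, "18" = 2, "19" = 5, "20" = 4, "21" = 4, "22" = 2)
  btw <- c("1" = 60, "2" = 20, "3" = 80, "4" = 55, "5" = 50,
           "6" = 10, "7" = 6, "8" = 4, "9" = 0,
           "10" = 25, "11" = 15, "12" = 10, "13" = 120, "14" = 110,
           "15" = 100, "16" = 5,
           "17" = 8, "18" = 2, "19" = 40, "20" = 30, "21" = 70, "22" = 1)
  comm <- c(rep("C1", 9), rep("C2", 7), rep("C3", 6))
  names(comm) <- as.character(1:22)
  list(
    degree = structure(deg, measure = "degree", class = "centrality_scores"),
    betweenness = structure(btw, measure = "betweenness",
                            class = "centrality_scores"),
    partition = partition(comm)
  )
}
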