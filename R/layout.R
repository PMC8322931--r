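# Region/tile layout: contiguous codon intervals used for regional
# mutagenesis (4 regions) and tile-based sequencing (19 tiles by default).

#' Construct a region/tile layout
#'
#' Splits `n_positions` codons into contiguous regions, each subdivided into
#' contiguous tiles. The default mirrors a four-region design with
#' 4/4/5/6 tiles per region (19 tiles in total); boundaries are near-equal
#' splits since no exact boundaries are published for the assay this models.
#'
#' @param n_positions Number of codons (protein length).
#' @param n_regions Number of mutagenesis regions.
#' @param tiles_per_region Integer vector, tiles in each region.
#' @return An object of class `region_layout` with a `tiles` tibble
#'   (`tile`, `region`, `start`, `end`) and a `regions` tibble.
#' @export
region_layout <- function(n_positions = 656L, n_regions = 4L,
                          tiles_per_region = c(4L, 4L, 5L, 6L)) {
  abort_if(length(tiles_per_region) != n_regions,
           "`tiles_per_region` must have one entry per region.")
  abort_if(n_positions < sum(tiles_per_region),
           "More tiles than positions.")
  region_sizes <- even_split(n_positions, n_regions)
  region_end <- cumsum(region_sizes)
  region_start <- c(1L, head(region_end, -1L) + 1L)
  tiles <- purrr::map_dfr(seq_len(n_regions), function(r) {
    sizes <- even_split(region_sizes[r], tiles_per_region[r])
    end <- region_start[r] - 1L + cumsum(sizes)
    start <- c(region_start[r], head(end, -1L) + 1L)
    tibble::tibble(region = r, start = start, end = end)
  })
  tiles <- dplyr::mutate(tiles, tile = dplyr::row_number(), .before = 1L)
  structure(
    list(
      n_positions = n_positions,
      regions = tibble::tibble(region = seq_len(n_regions),
                               start = region_start, end = region_end),
      tiles = tiles
    ),
    class = "region_layout"
  )
}

even_split <- function(n, k) {
  base <- n %/% k
  extra <- n %% k
  as.integer(base + (seq_len(k) <= extra))
}

#' @export
print.region_layout <- function(x, ...) {
  cat("<region_layout> ", x$n_positions, " positions, ",
      nrow(x$regions), " regions, ", nrow(x$tiles), " tiles\n", sep = "")
  invisible(x)
}

#' Locate positions in a region/tile layout
#'
#' @param position Integer vector of codon positions.
#' @param layout A [region_layout()].
#' @return A tibble with columns `position`, `region`, `tile`.
#' @export
locate_variant <- function(position, layout) {
  abort_if(any(position < 1L | position > layout$n_positions),
           "Position outside the layout coverage.")
  idx <- findInterval(position, layout$tiles$start)
  tibble::tibble(
    position = position,
    region = layout$tiles$region[idx],
    tile = layout$tiles$tile[idx]
  )
}
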