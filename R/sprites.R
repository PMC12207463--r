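## Sprite sheet: every tile is an 8x8x3 uint8-valued array (stored as numeric).
## The world is drawn exclusively from these tiles, so the observation window of
## 11x11 sprites is exactly 88x88 RGB pixels.

SPRITE_PX <- 8L

#' Default palette for the sprite sheet
#'
#' Group body colors default to the red/blue pair `[150,0,0]` / `[0,0,150]`;
#' the similarity sweep replaces them with the purple pairs
#' `[150,0,50]`/`[50,0,150]` and `[150,0,100]`/`[100,0,150]`. Resource colors
#' are brighter than any body color so resources and avatars never alias.
#'
#' @return named list of RGB triples (0-255).
#' @export
default_palette <- function() {
  list(
    background = c(20, 20, 20),
    void       = c(0, 0, 0),
    wall       = c(110, 110, 110),
    resources  = list(c(255, 80, 80), c(80, 255, 80), c(80, 80, 255)),
    headband   = c(255, 255, 255),
    pixel_bright = c(255, 255, 0),
    pixel_dark   = c(80, 80, 0)
  )
}

solid_tile <- function(rgb) {
  array(rep(as.numeric(rgb), each = SPRITE_PX * SPRITE_PX),
        dim = c(SPRITE_PX, SPRITE_PX, 3L))
}

resource_tile <- function(rgb, background) {
  tile <- solid_tile(background)
  tile[3:6, 3:6, ] <- rep(as.numeric(rgb), each = 16L)
  tile
}

#' Compose an avatar sprite tile
#'
#' Builds the 8x8 RGB tile for one agent: a body-colored block on the
#' background, an optional "ready to interact" headband drawn as the top sprite
#' row at reduced opacity (a transparent band over whatever is underneath), and
#' an optional single individuation pixel at a fixed coordinate. Toggling
#' `ready` changes only the headband row; supplying `individuation_pixel`
#' changes exactly one pixel.
#'
#' @param body_color RGB triple (0-255) of the agent's group.
#' @param ready logical; draw the ready headband.
#' @param individuation_pixel optional RGB triple for the unique pixel
#'   (e.g. the bright `[255,255,0]` or dark `[80,80,0]` variants), or `NULL`.
#' @param palette palette list, see [default_palette()].
#' @return 8x8x3 numeric array of RGB values in 0-255.
#' @export
#' @examples
#' tile <- compose_avatar_sprite(c(150, 0, 0), ready = TRUE)
#' dim(tile)
compose_avatar_sprite <- function(body_color, ready = FALSE,
                                  individuation_pixel = NULL,
                                  palette = default_palette()) {
  stopifnot(length(body_color) == 3L, all(body_color >= 0), all(body_color <= 255))
  tile <- solid_tile(palette$background)
  tile[2:8, 2:7, ] <- rep(as.numeric(body_color), each = 7L * 6L)
  if (!is.null(individuation_pixel)) {
    stopifnot(length(individuation_pixel) == 3L)
    tile[IND_PIXEL_COORD[1L], IND_PIXEL_COORD[2L], ] <- as.numeric(individuation_pixel)
  }
  if (isTRUE(ready)) {
    tile[1L, , ] <- 0.5 * tile[1L, , ] +
      0.5 * rep(as.numeric(palette$headband), each = SPRITE_PX)
  }
  tile
}

## Fixed sprite coordinate of the individuation pixel (row, col), inside the body.
IND_PIXEL_COORD <- c(4L, 4L)

#' Build the sprite sheet for a run
#'
#' Pre-renders all tiles used by the observation renderer: background, void
#' (out-of-map), wall, the three resource colors, and the four avatar variants
#' (ready x not-ready) per distinct (body color, individuation pixel) pair are
#' composed lazily by the renderer via [compose_avatar_sprite()].
#'
#' @param palette palette list.
#' @return list of named tiles plus the palette (serialisable for run manifests).
#' @export
sprite_sheet <- function(palette = default_palette()) {
  list(
    palette = palette,
    background = solid_tile(palette$background),
    void = solid_tile(palette$void),
    wall = solid_tile(palette$wall),
    resources = lapply(palette$resources, resource_tile, background = palette$background)
  )
}
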