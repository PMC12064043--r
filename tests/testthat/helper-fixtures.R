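# Shared builders: toy palettes/scenes and the published-table infrastructure
# account, assembled once per test run.

toy_palette <- function(ids = c(41L, 51L, 61L, 131L)) {
  p <- default_palette()
  p[p$class_id %in% ids, ]
}

toy_config <- function(grid = c(20, 20), ids = c(41L, 51L, 61L, 131L),
                       seed = 11L, ...) {
  pal <- toy_palette(ids)
  scene_config(grid_shape = grid, palette = pal,
               class_params = default_class_params(),
               n_watersheds = 4, seed = seed, ...)
}

mkc_infra_account <- function() {
  infra <- mkc_infrastructure()
  land <- rbind(
    data.frame(selu_id = infra$selu_id, date = "opening", GBLI = infra$GBLI13,
               HNVI = infra$HNVI13, FI = infra$FI13, NLEP = infra$NLEP13),
    data.frame(selu_id = infra$selu_id, date = "closing", GBLI = infra$GBLI18,
               HNVI = infra$HNVI18, FI = infra$FI18, NLEP = infra$NLEP18)
  )
  riv <- rbind(
    data.frame(selu_id = infra$selu_id, date = "opening", RAWI = infra$RAWI13,
               HNVI_riv = infra$HNVI_riv13, frag_riv = infra$frag_riv13,
               NREP = infra$NREP13),
    data.frame(selu_id = infra$selu_id, date = "closing", RAWI = infra$RAWI18,
               HNVI_riv = infra$HNVI_riv18, frag_riv = infra$frag_riv18,
               NREP = infra$NREP18)
  )
  assemble_infra_account(land, riv,
                         EHI = stats::setNames(infra$EHI, infra$selu_id),
                         adjustment = unname(attr(infra, "adjustment")))
}

mkc_capability_frame <- function(year) {
  x <- mkc_capability(year)
  data.frame(selu_id = x$selu_id, C10 = x$C10, CIUV = x$CIUV, W6 = x$W6,
             W15 = x$W15, TEIP_adj = x$TEIP_adj, EIIUV = x$EIIUV,
             stringsAsFactors = FALSE)
}

# Brute-force oracle: per-pixel enumeration of the land-cover account.
brute_force_account <- function(opening, closing, pixel_area, rules) {
  ids <- sort(unique(c(opening[!is.na(opening)], closing[!is.na(closing)])))
  chr <- as.character(ids)
  lf <- paste0("lf", 1:7)
  open_st <- stats::setNames(rep(0, length(ids)), chr)
  close_st <- open_st
  formation <- matrix(0, 7, length(ids), dimnames = list(lf, chr))
  consumption <- formation
  for (i in seq_len(nrow(opening))) {
    for (j in seq_len(ncol(opening))) {
      a <- opening[i, j]; b <- closing[i, j]
      if (is.na(a) || is.na(b)) next
      open_st[as.character(a)] <- open_st[as.character(a)] + pixel_area
      close_st[as.character(b)] <- close_st[as.character(b)] + pixel_area
      if (a != b) {
        code <- rules[as.character(a), as.character(b)]
        if (code != "lf0") {
          formation[code, as.character(b)] <-
            formation[code, as.character(b)] + pixel_area
          consumption[code, as.character(a)] <-
            consumption[code, as.character(a)] + pixel_area
        }
      }
    }
  }
  list(opening = open_st, closing = close_st, formation = formation,
       consumption = consumption)
}
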