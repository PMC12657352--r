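# Synthetic aortic network model: vessel segments, the healthy template,
# lesion insertion (ostial stenosis, fusiform aneurysm, dissection), digital
# repair, and cohort generation.
#
# Networks are abstract directed graphs; trunk segments carry a 0-based axial
# station index (inlet = station 0) instead of 3D coordinates.

#' Canonical aortic branch names
#'
#' The twelve named outflow branches of the thoraco-abdominal aorta:
#' brachiocephalic trunk (BT), left common carotid (LCC), left subclavian
#' (LSA), celiac trunk (CT), superior mesenteric (SMA), left/right renal
#' (LRA/RRA), inferior mesenteric (IMA) and the external/internal iliac
#' arteries of both sides (LEIA, LIIA, REIA, RIIA).
#'
#' @export
BRANCH_NAMES <- c("BT", "LCC", "LSA", "CT", "SMA", "LRA", "RRA", "IMA",
                  "LEIA", "LIIA", "REIA", "RIIA")

SUPRA_AORTIC <- c("BT", "LCC", "LSA")
LUMEN_TAGS <- c("NONE", "TL", "FL", "TEAR")

#' Stenosis descriptor for a vessel segment
#'
#' A reduced-order stand-in for a focal narrowing: the ratio of stenotic to
#' reference cross-sectional area plus an empirical turbulent loss
#' coefficient entering the quadratic pressure-loss term.
#'
#' @param area_ratio stenotic area / reference area, in (0, 1].
#' @param kt dimensionless turbulent loss coefficient (>= 0); the default
#'   1.52 is the classic empirical value for blunt stenoses.
#' @return object of class `stenosis_spec`.
#' @export
stenosis_spec <- function(area_ratio, kt = 1.52) {
  if (!is.numeric(area_ratio) || length(area_ratio) != 1L ||
      is.na(area_ratio) || area_ratio <= 0 || area_ratio > 1)
    fd_validation_error("stenosis area_ratio must be in (0, 1]")
  if (!is.numeric(kt) || length(kt) != 1L || is.na(kt) || kt < 0)
    fd_validation_error("stenosis kt must be >= 0")
  structure(list(area_ratio = area_ratio, kt = kt), class = "stenosis_spec")
}

# internal constructor for the segment table
new_segment_table <- function(id, from, to, length_cm, radius_cm,
                              lumen_tag = "NONE", branch = NA_character_,
                              station = NA_integer_,
                              sten_area_ratio = NA_real_, sten_kt = NA_real_,
                              dilation = 1) {
  data.frame(id = id, from = from, to = to,
             length_cm = length_cm, radius_cm = radius_cm,
             lumen_tag = lumen_tag, branch = branch,
             station = as.integer(station),
             sten_area_ratio = sten_area_ratio, sten_kt = sten_kt,
             dilation = dilation, stringsAsFactors = FALSE)
}

#' Assemble an aortic network
#'
#' @param segments data frame with columns `id`, `from`, `to`, `length_cm`,
#'   `radius_cm`, `lumen_tag`, `branch`, `station`, `sten_area_ratio`,
#'   `sten_kt`, `dilation`.
#' @param inlet inlet node id.
#' @param outlets named character vector, branch name -> outlet node id.
#' @param validate run full schema validation (default TRUE).
#' @return object of class `aortic_network` with fields `nodes`, `segments`,
#'   `inlet`, `outlets` and `branch_inlet_area` (cm^2, pi r^2 of each
#'   branch's first segment).
#' @export
aortic_network <- function(segments, inlet, outlets, validate = TRUE) {
  nodes <- unique(c(segments$from, segments$to, inlet, unname(outlets)))
  net <- structure(list(nodes = nodes, segments = segments, inlet = inlet,
                        outlets = outlets,
                        branch_inlet_area = branch_inlet_areas(segments, outlets)),
                   class = "aortic_network")
  if (validate) validate_network(net)
  net
}

branch_inlet_areas <- function(segments, outlets) {
  vapply(names(outlets), function(b) {
    rows <- segments[!is.na(segments$branch) & segments$branch == b, ]
    if (nrow(rows) == 0L) return(NA_real_)
    pi * rows$radius_cm[1L]^2
  }, numeric(1))
}

#' Validate an aortic network
#'
#' Checks the structural invariants: positive radii and lengths, no
#' self-loop segments, recognized lumen tags, unique branch names drawn from
#' the canonical vocabulary, weak connectivity, and reachability of every
#' outlet from the inlet.
#'
#' @param net an `aortic_network`.
#' @return the network, invisibly; signals a validation error otherwise.
#' @export
validate_network <- function(net) {
  seg <- net$segments
  if (any(seg$radius_cm <= 0) || any(!is.finite(seg$radius_cm)))
    fd_validation_error("segment field 'radius_cm' must be positive and finite")
  if (any(seg$length_cm <= 0) || any(!is.finite(seg$length_cm)))
    fd_validation_error("segment field 'length_cm' must be positive and finite")
  if (any(seg$from == seg$to))
    fd_validation_error("segment field 'from'/'to': self-loop segment")
  if (anyDuplicated(seg$id))
    fd_validation_error("segment field 'id' must be unique")
  if (!all(seg$lumen_tag %in% LUMEN_TAGS))
    fd_validation_error(sprintf("unrecognized lumen_tag: %s",
      paste(setdiff(seg$lumen_tag, LUMEN_TAGS), collapse = ", ")))
  ok <- is.na(seg$sten_area_ratio) |
    (seg$sten_area_ratio > 0 & seg$sten_area_ratio <= 1)
  if (!all(ok))
    fd_validation_error("segment field 'sten_area_ratio' must be in (0, 1]")
  if (anyDuplicated(names(net$outlets)))
    fd_validation_error("outlet branch names must be unique")
  if (!all(names(net$outlets) %in% BRANCH_NAMES))
    fd_validation_error(sprintf("unknown branch name(s): %s",
      paste(setdiff(names(net$outlets), BRANCH_NAMES), collapse = ", ")))
  if (!(net$inlet %in% c(seg$from, seg$to)))
    fd_validation_error("inlet node not present in any segment")
  if (!all(net$outlets %in% c(seg$from, seg$to)))
    fd_validation_error("outlet node(s) not present in any segment")
  # weak connectivity + outlet reachability (undirected BFS from inlet;
  # a 0D network conducts both ways, so undirected reachability is the
  # physically meaningful notion)
  adj <- split(c(seg$to, seg$from), c(seg$from, seg$to))
  seen <- net$inlet
  frontier <- net$inlet
  while (length(frontier)) {
    nxt <- setdiff(unique(unlist(adj[frontier], use.names = FALSE)), seen)
    seen <- c(seen, nxt)
    frontier <- nxt
  }
  if (!all(net$nodes %in% seen))
    fd_validation_error("network is not weakly connected")
  if (!all(net$outlets %in% seen))
    fd_validation_error("outlet(s) unreachable from inlet")
  invisible(net)
}

# default morphometry for the healthy template (radii/lengths in cm);
# values are typical adult thoraco-abdominal dimensions
default_morphometry <- function() {
  list(
    trunk = data.frame(
      id        = paste0("AO", 0:9),
      length_cm = c(5, 1.5, 1.5, 6, 12, 1.5, 1.5, 1, 4, 4),
      radius_cm = c(1.50, 1.45, 1.42, 1.30, 1.10, 0.95, 0.90, 0.88, 0.85, 0.80)
    ),
    # branch origin = distal node of the trunk station listed in `origin`
    branches = data.frame(
      branch    = c("BT", "LCC", "LSA", "CT", "SMA", "LRA", "RRA", "IMA"),
      origin    = c(0L, 1L, 2L, 4L, 5L, 6L, 7L, 8L),
      length_cm = c(4, 10, 5, 3, 5, 4, 4.5, 4),
      radius_cm = c(0.65, 0.40, 0.55, 0.40, 0.40, 0.30, 0.30, 0.20)
    ),
    iliac = list(common_length_cm = 4, common_radius_cm = 0.55,
                 ext_length_cm = 8, ext_radius_cm = 0.40,
                 int_length_cm = 6, int_radius_cm = 0.30),
    jitter_sd = 0.03   # log-normal sd applied to radii and lengths
  )
}

#' Build a synthetic healthy aortic template
#'
#' Constructs a lesion-free aortic tree with all twelve canonical branches:
#' a tapering trunk of ten stations from the ascending aorta to the iliac
#' bifurcation, the three supra-aortic branches on the arch, four visceral
#' branches plus the inferior mesenteric artery on the abdominal trunk, and
#' paired common/external/internal iliac arteries. Radii and lengths start
#' from a documented typical-adult morphometry table and receive a small
#' multiplicative log-normal jitter so generated cohorts vary anatomically.
#'
#' @param morph_params optional list overriding entries of the default
#'   morphometry (`trunk`, `branches`, `iliac`, `jitter_sd`); see
#'   `flowdiv:::default_morphometry()`.
#' @param seed integer seed for the jitter; `NULL` disables jitter.
#' @return a validated `aortic_network` with 12 outlets.
#' @export
build_healthy_template <- function(morph_params = list(), seed = NULL) {
  mp <- utils::modifyList(default_morphometry(), morph_params)
  if (any(mp$trunk$radius_cm <= 0) || any(mp$trunk$length_cm <= 0) ||
      any(mp$branches$radius_cm <= 0) || any(mp$branches$length_cm <= 0) ||
      any(unlist(mp$iliac) <= 0))
    fd_validation_error("morphometry radii and lengths must be positive")
  if (mp$jitter_sd < 0) fd_validation_error("jitter_sd must be >= 0")

  jit <- function(x) x * exp(stats::rnorm(length(x), 0, mp$jitter_sd))
  with_seed(seed, {
    trunk_r <- if (is.null(seed)) mp$trunk$radius_cm else jit(mp$trunk$radius_cm)
    trunk_l <- if (is.null(seed)) mp$trunk$length_cm else jit(mp$trunk$length_cm)
    br_r <- if (is.null(seed)) mp$branches$radius_cm else jit(mp$branches$radius_cm)
    br_l <- if (is.null(seed)) mp$branches$length_cm else jit(mp$branches$length_cm)
    il <- mp$iliac
    il_r <- if (is.null(seed)) rep(c(il$common_radius_cm, il$ext_radius_cm,
                                     il$int_radius_cm), 2)
            else jit(rep(c(il$common_radius_cm, il$ext_radius_cm,
                           il$int_radius_cm), 2))
    il_l <- rep(c(il$common_length_cm, il$ext_length_cm, il$int_length_cm), 2)
  })

  k <- nrow(mp$trunk)
  trunk_nodes <- sprintf("n%02d", 0:k)   # n00 (inlet) .. n10 (iliac bif.)
  segs <- new_segment_table(
    id = mp$trunk$id, from = trunk_nodes[1:k], to = trunk_nodes[2:(k + 1)],
    length_cm = trunk_l, radius_cm = trunk_r, station = 0:(k - 1))

  br <- mp$branches
  outlets <- character(0)
  for (i in seq_len(nrow(br))) {
    b <- br$branch[i]
    node <- paste0("n", b)
    segs <- rbind(segs, new_segment_table(
      id = paste0(b, "_1"), from = trunk_nodes[br$origin[i] + 2L], to = node,
      length_cm = br_l[i], radius_cm = br_r[i], branch = b))
    outlets[b] <- node
  }

  bif <- trunk_nodes[k + 1L]
  for (s in c("L", "R")) {
    off <- if (s == "L") 0L else 3L
    cia <- paste0("n", s, "CIA")
    segs <- rbind(
      segs,
      new_segment_table(id = paste0(s, "CIA"), from = bif, to = cia,
                        length_cm = il_l[off + 1L], radius_cm = il_r[off + 1L]),
      new_segment_table(id = paste0(s, "EIA_1"), from = cia,
                        to = paste0("n", s, "EIA"),
                        length_cm = il_l[off + 2L], radius_cm = il_r[off + 2L],
                        branch = paste0(s, "EIA")),
      new_segment_table(id = paste0(s, "IIA_1"), from = cia,
                        to = paste0("n", s, "IIA"),
                        length_cm = il_l[off + 3L], radius_cm = il_r[off + 3L],
                        branch = paste0(s, "IIA")))
    outlets[paste0(s, "EIA")] <- paste0("n", s, "EIA")
    outlets[paste0(s, "IIA")] <- paste0("n", s, "IIA")
  }

  aortic_network(segs, inlet = trunk_nodes[1L],
                 outlets = outlets[BRANCH_NAMES])
}

#' Describe a vascular lesion
#'
#' @param kind one of `"OSTIAL_STENOSIS"`, `"FUSIFORM_ANEURYSM"`,
#'   `"DISSECTION"`.
#' @param target branch name (stenosis or branch aneurysm) or, for trunk
#'   aneurysms and dissections, an integer vector of trunk station indices
#'   `c(first, last)` (0-based, inclusive).
#' @param area_ratio stenotic/reference area for `OSTIAL_STENOSIS`, in (0,1].
#' @param kt turbulent loss coefficient for the stenosis.
#' @param dilation radius multiplier (> 1) for `FUSIFORM_ANEURYSM`.
#' @param tears trunk station indices carrying intimal tears (`DISSECTION`);
#'   must lie within `target` and contain at least one station.
#' @param tear_radius_cm radius of each tear channel (recycled).
#' @param tl_area_frac fraction of the (expanded) lumen area kept by the true
#'   lumen; default 0.43, matching dissections whose false lumen is the
#'   larger channel.
#' @param expansion total cross-sectional area multiplier of the dissected
#'   trunk relative to health (default 1.2; dissection dilates the aorta).
#' @param fl_branches branches whose origins are re-anchored onto the false
#'   lumen (they must originate inside the flap extent).
#' @param seed integer stored for provenance.
#' @return object of class `lesion_spec`.
#' @export
lesion_spec <- function(kind, target, area_ratio = NULL, kt = 1.52,
                        dilation = NULL, tears = NULL, tear_radius_cm = 0.35,
                        tl_area_frac = 0.43, expansion = 1.2,
                        fl_branches = character(0), seed = NULL) {
  kind <- match.arg(kind, c("OSTIAL_STENOSIS", "FUSIFORM_ANEURYSM", "DISSECTION"))
  if (kind == "OSTIAL_STENOSIS") {
    if (is.null(area_ratio)) fd_validation_error("stenosis requires area_ratio")
    stenosis_spec(area_ratio, kt)  # range check
  }
  if (kind == "FUSIFORM_ANEURYSM") {
    if (is.null(dilation) || dilation <= 1 || dilation > 4)
      fd_validation_error("aneurysm dilation must be in (1, 4]")
  }
  if (kind == "DISSECTION") {
    if (length(target) != 2L || !is.numeric(target) || target[1] > target[2])
      fd_validation_error("dissection target must be c(first, last) trunk stations")
    if (is.null(tears) || length(tears) < 1L)
      fd_validation_error("dissection requires at least one tear station")
    if (!all(tears >= target[1] & tears <= target[2]))
      fd_validation_error("tear station outside flap extent")
    if (tl_area_frac <= 0 || tl_area_frac >= 1)
      fd_validation_error("tl_area_frac must be in (0, 1)")
    if (any(tear_radius_cm <= 0)) fd_validation_error("tear radius must be > 0")
  }
  structure(list(kind = kind, target = target, area_ratio = area_ratio,
                 kt = kt, dilation = dilation, tears = tears,
                 tear_radius_cm = tear_radius_cm,
                 tl_area_frac = tl_area_frac, expansion = expansion,
                 fl_branches = fl_branches, seed = seed),
            class = "lesion_spec")
}

first_branch_row <- function(seg, branch) {
  idx <- which(!is.na(seg$branch) & seg$branch == branch)
  if (length(idx) == 0L)
    fd_validation_error(sprintf("unknown lesion target branch '%s'", branch))
  idx[1L]
}

#' Insert a lesion into a network
#'
#' `OSTIAL_STENOSIS` attaches the stenosis descriptor to the first segment of
#' the named branch. `FUSIFORM_ANEURYSM` multiplies radii over the target
#' branch or trunk stations and records the factor. `DISSECTION` splits the
#' flap-extent trunk stations into parallel true-lumen/false-lumen chains,
#' cross-linked by tear segments at the stated stations; branches listed in
#' `fl_branches` are re-anchored onto the false lumen.
#'
#' @param net an `aortic_network`.
#' @param lesion a `lesion_spec`.
#' @return a new validated `aortic_network`; outlet names are unchanged.
#' @export
apply_lesion <- function(net, lesion) {
  stopifnot(inherits(net, "aortic_network"), inherits(lesion, "lesion_spec"))
  seg <- net$segments
  if (lesion$kind == "OSTIAL_STENOSIS") {
    i <- first_branch_row(seg, lesion$target)
    seg$sten_area_ratio[i] <- lesion$area_ratio
    seg$sten_kt[i] <- lesion$kt
  } else if (lesion$kind == "FUSIFORM_ANEURYSM") {
    if (is.character(lesion$target)) {
      idx <- which(!is.na(seg$branch) & seg$branch == lesion$target)
      if (length(idx) == 0L)
        fd_validation_error(sprintf("unknown lesion target branch '%s'",
                                    lesion$target))
    } else {
      idx <- which(!is.na(seg$station) &
                     seg$station >= lesion$target[1] &
                     seg$station <= lesion$target[2])
      if (length(idx) == 0L)
        fd_validation_error("no trunk stations in aneurysm target range")
    }
    seg$radius_cm[idx] <- seg$radius_cm[idx] * lesion$dilation
    seg$dilation[idx] <- seg$dilation[idx] * lesion$dilation
  } else {  # DISSECTION
    seg <- dissect_trunk(seg, lesion)
  }
  aortic_network(seg, net$inlet, net$outlets)
}

# split trunk stations [lo, hi] into TL/FL chains with TEAR cross-links
dissect_trunk <- function(seg, lesion) {
  lo <- lesion$target[1]; hi <- lesion$target[2]
  idx <- which(!is.na(seg$station) & seg$station >= lo & seg$station <= hi)
  if (length(idx) == 0L)
    fd_validation_error("no trunk stations in dissection flap extent")
  idx <- idx[order(seg$station[idx])]
  flap <- seg[idx, ]
  if (any(flap$lumen_tag != "NONE"))
    fd_validation_error("flap extent already dissected")

  r_tl <- flap$radius_cm * sqrt(lesion$tl_area_frac * lesion$expansion)
  r_fl <- flap$radius_cm * sqrt((1 - lesion$tl_area_frac) * lesion$expansion)

  fl_node <- function(n) paste0(n, "_FL")
  tl <- flap; tl$id <- paste0(flap$id, "_TL")
  tl$radius_cm <- r_tl; tl$lumen_tag <- "TL"
  fl <- flap; fl$id <- paste0(flap$id, "_FL")
  fl$from <- fl_node(flap$from); fl$to <- fl_node(flap$to)
  fl$radius_cm <- r_fl; fl$lumen_tag <- "FL"

  # tear at station t joins the distal node of that station's segments
  tear_rad <- rep_len(lesion$tear_radius_cm, length(lesion$tears))
  tears <- do.call(rbind, lapply(seq_along(lesion$tears), function(j) {
    t <- lesion$tears[j]
    at <- flap$to[match(t, flap$station)]
    new_segment_table(id = sprintf("TEAR_%d", t), from = at, to = fl_node(at),
                      length_cm = 0.5, radius_cm = tear_rad[j],
                      lumen_tag = "TEAR")
  }))

  out <- rbind(seg[-idx, ], tl, fl, tears)
  # re-anchor designated branches onto the false lumen
  for (b in lesion$fl_branches) {
    i <- first_branch_row(out, b)
    if (!(out$from[i] %in% flap$to))
      fd_validation_error(sprintf(
        "branch '%s' does not originate inside the flap extent", b))
    out$from[i] <- fl_node(out$from[i])
  }
  rownames(out) <- NULL
  out
}

#' Digitally repair a diseased network
#'
#' The network analogue of manual geometry repair: stenosis descriptors are
#' removed, aneurysmal dilation factors are reverted, and dissected
#' true/false lumen chains are merged back into a single trunk whose radius
#' at each station is interpolated (linearly in station index) between the
#' adjacent unaffected stations, then multiplied by a contraction factor.
#' Bifurcation nodes and branch names are preserved. Lesion-free networks are
#' returned unchanged.
#'
#' @param net a diseased `aortic_network`.
#' @param contraction radius multiplier applied to the merged dissection
#'   lumen (default 1 = no contraction); the dilated dissected aorta is
#'   usually contracted slightly toward healthy calibre.
#' @return a validated lesion-free `aortic_network`.
#' @export
repair <- function(net, contraction = 1) {
  stopifnot(inherits(net, "aortic_network"))
  if (contraction <= 0) fd_validation_error("contraction must be > 0")
  seg <- net$segments
  if (!all(seg$lumen_tag %in% LUMEN_TAGS))
    fd_validation_error("unrecognized lumen tags")

  # stenoses: drop the descriptor (radius field is unaffected by an ostial
  # stenosis, so neighbours need no interpolation)
  seg$sten_area_ratio <- NA_real_
  seg$sten_kt <- NA_real_
  # aneurysms: revert recorded dilation
  dil <- seg$dilation != 1
  seg$radius_cm[dil] <- seg$radius_cm[dil] / seg$dilation[dil]
  seg$dilation <- 1

  if (any(seg$lumen_tag != "NONE")) {
    # drop false lumen and tears, keep the true-lumen chain as the trunk
    seg <- seg[seg$lumen_tag != "FL" & seg$lumen_tag != "TEAR", ]
    tl <- which(seg$lumen_tag == "TL")
    st <- seg$station[tl]
    lo <- min(st); hi <- max(st)
    # bounding healthy radii from stations adjacent to the flap extent
    r_prox <- seg$radius_cm[match(lo - 1L, seg$station)]
    r_dist <- seg$radius_cm[match(hi + 1L, seg$station)]
    if (is.na(r_prox) && is.na(r_dist))
      fd_validation_error("no unaffected trunk stations adjacent to the flap")
    if (is.na(r_prox)) r_prox <- r_dist
    if (is.na(r_dist)) r_dist <- r_prox
    w <- (st - (lo - 1)) / (hi + 1 - (lo - 1))
    seg$radius_cm[tl] <- (r_prox * (1 - w) + r_dist * w) * contraction
    seg$lumen_tag[tl] <- "NONE"
    seg$id[tl] <- sub("_TL$", "", seg$id[tl])
    # re-anchor any false-lumen branches back onto the trunk nodes
    seg$from <- sub("_FL$", "", seg$from)
    seg$to <- sub("_FL$", "", seg$to)
  }
  rownames(seg) <- NULL
  aortic_network(seg, net$inlet, net$outlets)
}

#' Generate a cohort of diseased/reference network pairs
#'
#' Draws `n` jittered healthy templates, applies one lesion per subject
#' sampled from `lesion_menu`, and pairs each diseased network with its
#' digital repair.
#'
#' @param n number of subjects (>= 1).
#' @param lesion_menu list of `lesion_spec` objects to sample from; the
#'   default menu holds a celiac-trunk ostial stenosis, an infrarenal
#'   fusiform aneurysm, and a two-tear descending-aorta dissection.
#' @param seed integer seed controlling template jitter and menu sampling.
#' @param morph_params passed to [build_healthy_template()].
#' @return list of `n` lists with elements `diseased`, `reference`, `lesion`.
#' @export
generate_cohort <- function(n, lesion_menu = default_lesion_menu(), seed = 1L,
                            morph_params = list()) {
  if (!is.numeric(n) || length(n) != 1L || n < 1 || n != round(n))
    fd_validation_error("n must be an integer >= 1")
  if (length(lesion_menu) < 1L)
    fd_validation_error("lesion_menu must contain at least one lesion_spec")
  seeds <- with_seed(seed, sample.int(2^31 - 2, 2 * n))
  picks <- with_seed(seeds[n + 1L], sample.int(length(lesion_menu), n, replace = TRUE))
  lapply(seq_len(n), function(i) {
    healthy <- build_healthy_template(morph_params, seed = seeds[i])
    lesion <- lesion_menu[[picks[i]]]
    diseased <- apply_lesion(healthy, lesion)
    list(diseased = diseased, reference = repair(diseased), lesion = lesion)
  })
}

#' @rdname generate_cohort
#' @export
default_lesion_menu <- function() {
  list(
    lesion_spec("OSTIAL_STENOSIS", "CT", area_ratio = 0.3),
    lesion_spec("FUSIFORM_ANEURYSM", c(8L, 9L), dilation = 1.8),
    lesion_spec("DISSECTION", c(4L, 8L), tears = c(4L, 8L))
  )
}

#' @export
print.aortic_network <- function(x, ...) {
  cat(sprintf("aortic_network: %d nodes, %d segments, %d outlets (%s)\n",
              length(x$nodes), nrow(x$segments), length(x$outlets),
              paste(names(x$outlets), collapse = ", ")))
  n_sten <- sum(!is.na(x$segments$sten_area_ratio))
  n_dis <- sum(x$segments$lumen_tag != "NONE")
  if (n_sten) cat(sprintf("  stenosed segments: %d\n", n_sten))
  if (n_dis) cat(sprintf("  dissection segments (TL/FL/TEAR): %d\n", n_dis))
  invisible(x)
}
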