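# Gated axial attention: 1-D self-attention along a single spatial axis
# with learned relative-position tables on query, key and value, each term
# scaled by a learnable scalar gate. The gating lets the network fade
# positional terms in or out, which stabilizes training on small datasets.

AXES <- c(depth = 3L, height = 4L, width = 5L)

#' Query/key/value projection parameters
#'
#' Bias-free per-voxel linear projections from `in_channels` to
#' `heads * head_dim` channels.
#'
#' @param in_channels Input channel count.
#' @param heads Number of attention heads.
#' @param head_dim Per-head embedding dimension.
#' @param init `"random"` (default) or `"identity"` (requires
#'   `in_channels == heads * head_dim`).
#' @return List with matrices `Wq`, `Wk`, `Wv` of shape `(heads*head_dim, in_channels)`.
#' @export
qkv_projections <- function(in_channels, heads, head_dim, init = "random") {
  Z <- heads * head_dim
  mk <- function() {
    if (init == "identity") {
      if (Z != in_channels)
        stop("identity projections need in_channels == heads * head_dim")
      diag(Z)
    } else {
      matrix(stats::rnorm(Z * in_channels, sd = 1 / sqrt(in_channels)), Z, in_channels)
    }
  }
  list(Wq = mk(), Wk = mk(), Wv = mk())
}

#' Relative-position tables and gates for one axis
#'
#' Tables are indexed by (query position, key position) with one slice per
#' head-dim coordinate; they are shared across heads. Gates
#' `(Gq, Gk, Gv1, Gv2)` scale the positional query/key terms and the two
#' value terms.
#'
#' @param axis_len Spatial extent the axis attends over.
#' @param head_dim Per-head embedding dimension.
#' @param gate_init Initial value for all four gates.
#' @return List with arrays `rq`, `rk`, `rv` of dim `(axis_len, axis_len,
#'   head_dim)` and numeric `gates = c(Gq, Gk, Gv1, Gv2)`.
#' @export
axial_tables <- function(axis_len, head_dim, gate_init = 1) {
  mk <- function() array(stats::rnorm(axis_len^2 * head_dim, sd = head_dim^(-1 / 2)),
                         c(axis_len, axis_len, head_dim))
  list(rq = mk(), rk = mk(), rv = mk(), gates = rep(gate_init, 4))
}

#' Full per-axis attention parameter set
#'
#' Convenience constructor combining [qkv_projections()] and
#' [axial_tables()] for standalone use of [gated_axial_attention()].
#'
#' @inheritParams qkv_projections
#' @inheritParams axial_tables
#' @export
axial_params <- function(in_channels, heads, head_dim, axis_len,
                         init = "random", gate_init = 1) {
  c(qkv_projections(in_channels, heads, head_dim, init = init),
    axial_tables(axis_len, head_dim, gate_init = gate_init),
    list(heads = heads, head_dim = head_dim))
}

#' Embed a volume into query, key and value
#'
#' Per-voxel bias-free linear maps (Volume in, Volume out with
#' `heads * head_dim` channels).
#'
#' @param x Volume `(N, C, D, H, W)`.
#' @param p Parameter list with `Wq`, `Wk`, `Wv` (see [qkv_projections()]).
#' @return List of volumes `q`, `k`, `v`.
#' @export
embed_qkv <- function(x, p) {
  C <- dim(pn_val(x))[2]
  for (nm in c("Wq", "Wk", "Wv")) {
    W <- pn_val(p[[nm]])
    if (is.null(dim(W))) dim(W) <- c(1L, length(W))
    if (ncol(W) != C)
      stop(sprintf("embed_qkv: projection %s expects %d input channels, input has %d",
                   nm, ncol(W), C))
  }
  list(q = op_conv1x1(x, p$Wq),
       k = op_conv1x1(x, p$Wk),
       v = op_conv1x1(x, p$Wv))
}

# fold (N, Z, D, H, W) -> (head_dim, L, M) for attention along `axis`,
# M enumerating (batch, head, off-axis positions); single-pass compiled
# repack, whose backward is the inverse repack
axial_fold <- function(x, axis, heads, head_dim) {
  d <- dim(pn_val(x))
  ax <- AXES[[axis]] - 2L
  y <- .cpp_axial_fold(pn_val(x), ax, heads, head_dim)
  pn_make(y, list(x), function(g) {
    list(.cpp_axial_unfold(g, ax, heads, head_dim, as.integer(d)))
  })
}

axial_unfold <- function(y, axis, heads, head_dim, d) {
  ax <- AXES[[axis]] - 2L
  out <- .cpp_axial_unfold(pn_val(y), ax, heads, head_dim, as.integer(d))
  pn_make(out, list(y), function(g) {
    list(.cpp_axial_fold(g, ax, heads, head_dim))
  })
}

# core attention on folded (dm, L, M) arrays
op_axial_core <- function(q, k, v, rq, rk, rv, gates) {
  qv <- pn_val(q); kv <- pn_val(k); vv <- pn_val(v)
  rqv <- pn_val(rq); rkv <- pn_val(rk); rvv <- pn_val(rv)
  gv <- pn_val(gates)
  L <- dim(qv)[2]
  if (dim(rqv)[1] != L)
    stop(sprintf("axial attention: positional table length %d does not match axis extent %d",
                 dim(rqv)[1], L))
  y <- .cpp_axial_attn_fwd(qv, kv, vv, rqv, rkv, rvv, gv)
  pn_make(y, list(q, k, v, rq, rk, rv, gates), function(g) {
    gr <- .cpp_axial_attn_bwd(qv, kv, vv, rqv, rkv, rvv, gv, g)
    list(gr$dq, gr$dk, gr$dv, gr$drq, gr$drk, gr$drv, gr$dg)
  })
}

#' Gated axial attention along one spatial axis
#'
#' Runs 1-D gated positional self-attention along `axis` for every line of
#' the volume; all other coordinates (batch, head, the two off-axis
#' positions) index independent attention problems. At each output
#' position i,
#' \deqn{y_i = \sum_j \mathrm{softmax}_j\big(q_i^\top k_j + G_q\, q_i^\top r^q_{ij}
#'   + G_k\, k_j^\top r^k_{ij}\big)\,\big(G_{v1} v_j + G_{v2} r^v_{ij}\big).}
#'
#' @param qkv List with volumes `q`, `k`, `v` of shape
#'   `(N, heads*head_dim, D, H, W)` (see [embed_qkv()]).
#' @param axis One of `"depth"`, `"height"`, `"width"`.
#' @param p Parameter list with tables `rq`, `rk`, `rv` sized to the axis
#'   extent and `gates` (see [axial_tables()]).
#' @param heads,head_dim Head layout of the q/k/v channels.
#' @return Volume with the same shape as `q`.
#' @export
gated_axial_attention <- function(qkv, axis, p, heads, head_dim) {
  axis <- match.arg(axis, names(AXES))
  d <- dim(pn_val(qkv$q))
  qa <- axial_fold(qkv$q, axis, heads, head_dim)
  ka <- axial_fold(qkv$k, axis, heads, head_dim)
  va <- axial_fold(qkv$v, axis, heads, head_dim)
  y <- op_axial_core(qa, ka, va, p$rq, p$rk, p$rv, p$gates)
  axial_unfold(y, axis, heads, head_dim, d)
}

#' Count independent 1-D axial attention problems
#'
#' For attention along `axis`, every (batch, head, off-axis position)
#' tuple is an independent length-L attention problem. Also reports the
#' folded leading dimension `batch * first-off-axis-extent * heads` used
#' when lines along the other two axes are kept unfolded.
#'
#' @param cfg A [net_config()] (or any list with `heads`).
#' @param input_extents Spatial extents `c(D, H, W)`.
#' @param axis One of `"depth"`, `"height"`, `"width"`.
#' @param batch Batch size.
#' @return List with `problems` and `folded_leading`.
#' @export
count_axial_problems <- function(cfg, input_extents, axis, batch = 1L) {
  axis <- match.arg(axis, names(AXES))
  stopifnot(length(input_extents) == 3L, all(input_extents >= 1))
  i <- AXES[[axis]] - 2L
  off <- as.integer(input_extents[-i])
  list(problems = as.integer(as.integer(batch) * cfg$heads * prod(off)),
       folded_leading = as.integer(batch * off[1] * cfg$heads))
}
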