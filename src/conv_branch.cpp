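// Compiled kernels for the convolution/pooling branches.
//
// A branch is: valid conv (im2col + one GEMM per batch) -> ReLU ->
// inverted dropout -> a chain of non-overlapping max-pools -> flatten.
// Backward exploits that the gradient reaching the conv map is non-zero
// only at pooling argmax positions, so kernel gradients are accumulated
// sparsely from those positions.
//
// Layouts (0-based; maps position-fastest, then filter, then sample):
//   tflat:    side^2 x B, one column per cell, row-major image pixels
//   patchIdx: P0 x (m*n), pixel index of each kernel element per placement
//   poolIdx:  Pout x (p*q), input-position index of each window element
//   Pall:     (P0*B) x (m*n); sample b occupies rows [b*P0, (b+1)*P0)
//   features: B x (Pout*f), element (pos, fil) at column fil*Pout + pos
//   args[s]:  int vector, index o + Pout_s*(c + f*b); stage-1 entries are
//             -1 where ReLU or dropout zeroed the selected element (no
//             gradient flows there; the kept multiplier is 1/(1-p))

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

namespace {

// xorshift128+ PRNG: fast, portable, fully determined by its seed.
struct XorShift128 {
  uint64_t s0, s1;
  explicit XorShift128(double seed) {
    uint64_t x = static_cast<uint64_t>(seed);
    for (uint64_t* s : {&s0, &s1}) {  // splitmix64 state expansion
      x += 0x9e3779b97f4a7c15ULL;
      uint64_t z = x;
      z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
      z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
      *s = z ^ (z >> 31);
    }
    if (s0 == 0 && s1 == 0) s0 = 1;
  }
  double next() {
    uint64_t x = s0, y = s1;
    s0 = y;
    x ^= x << 23;
    s1 = x ^ y ^ (x >> 17) ^ (y >> 26);
    return static_cast<double>((s1 + y) >> 11) * (1.0 / 9007199254740992.0);
  }
};

arma::mat gatherAll(const arma::mat& tflat, const arma::umat& patchIdx) {
  const arma::uword B = tflat.n_cols;
  const arma::uword P0 = patchIdx.n_rows, mn = patchIdx.n_cols;
  arma::mat P(P0 * B, mn);
  for (arma::uword e = 0; e < mn; ++e) {
    double* dst = P.colptr(e);
    for (arma::uword b = 0; b < B; ++b) {
      const double* col = tflat.colptr(b);
      for (arma::uword i = 0; i < P0; ++i) *dst++ = col[patchIdx(i, e)];
    }
  }
  return P;
}

}  // namespace

// Forward pass of one branch over a batch of cells. The convolution runs
// as one im2col GEMM for the whole batch with ReLU/dropout fused into a
// single pass; pooling then walks each sample's stripe of the batch map.
// Returns the flattened features and, when cache = TRUE, the per-stage
// argmax indices backward needs.
// [[Rcpp::export(name = ".cppBranchForward")]]
List cppBranchForward(const arma::mat& tflat, const arma::umat& patchIdx,
                      const arma::mat& K, const arma::vec& bias,
                      const List& poolIdx, double dropout, bool training,
                      double dropSeed, bool cache) {
  const arma::uword B = tflat.n_cols, f = K.n_cols;
  const arma::uword P0 = patchIdx.n_rows;
  const int nStages = poolIdx.size();

  std::vector<arma::umat> pools;
  arma::uword maxPos = 0;
  for (int s = 0; s < nStages; ++s) {
    pools.push_back(as<arma::umat>(poolIdx[s]));
    maxPos = std::max(maxPos, pools[s].n_rows);
  }
  const arma::uword outPos = pools.back().n_rows;

  const bool doDrop = training && dropout > 0;
  const double invKeep = doDrop ? 1.0 / (1.0 - dropout) : 1.0;
  XorShift128 rng(dropSeed);

  // conv for the whole batch in one GEMM, ReLU/dropout fused in one pass
  arma::mat Z = gatherAll(tflat, patchIdx) * K;
  Z.each_row() += bias.t();
  if (doDrop) {
    for (arma::uword j = 0; j < Z.n_elem; ++j) {
      double v = Z[j] > 0 ? Z[j] : 0.0;
      if (v != 0.0 && rng.next() < dropout) v = 0.0;
      Z[j] = v * invKeep;
    }
  } else {
    for (arma::uword j = 0; j < Z.n_elem; ++j)
      if (Z[j] < 0) Z[j] = 0.0;
  }

  arma::mat feat(B, outPos * f);
  List argList(nStages);
  std::vector<int*> argPtr(nStages, nullptr);
  if (cache)
    for (int s = 0; s < nStages; ++s) {
      IntegerVector a(static_cast<R_xlen_t>(pools[s].n_rows) * f * B);
      argList[s] = a;
      argPtr[s] = INTEGER(a);
    }

  arma::mat buf1(maxPos, f), buf2(maxPos, f);
  for (arma::uword b = 0; b < B; ++b) {
    arma::mat* cur = nullptr;
    for (int s = 0; s < nStages; ++s) {
      const arma::umat& pw = pools[s];
      const arma::uword nOut = pw.n_rows;
      arma::mat& out = (cur == &buf1) ? buf2 : buf1;
      for (arma::uword c = 0; c < f; ++c) {
        // stage 1 reads sample b's stripe of the batch conv map
        const double* in = (s == 0) ? Z.colptr(c) + b * P0 : cur->colptr(c);
        for (arma::uword o = 0; o < nOut; ++o) {
          arma::uword bi = pw(o, 0);
          double bv = in[bi];
          for (arma::uword e = 1; e < pw.n_cols; ++e) {
            const double v = in[pw(o, e)];
            if (v > bv) { bv = v; bi = pw(o, e); }
          }
          out(o, c) = bv;
          if (cache)
            argPtr[s][o + nOut * (c + f * b)] =
              (s == 0 && bv <= 0) ? -1 : static_cast<int>(bi);
        }
      }
      cur = &out;
    }
    double* fr = feat.memptr();  // column-major fill of row b
    for (arma::uword c = 0; c < f; ++c)
      for (arma::uword o = 0; o < outPos; ++o)
        fr[b + B * (c * outPos + o)] = (*cur)(o, c);
  }

  List res = List::create(Named("feat") = feat);
  if (cache) res["args"] = argList;
  return res;
}

// Backward pass of one branch: gradients w.r.t. kernel and bias given the
// gradient at the flattened branch output. invKeep is the dropout scale
// used in the forward pass (1 when dropout was off).
// [[Rcpp::export(name = ".cppBranchBackward")]]
List cppBranchBackward(const arma::mat& tflat, const arma::umat& patchIdx,
                       const arma::mat& Gfeat, const List& args,
                       const List& poolIdx, int filters, double invKeep) {
  const arma::uword B = tflat.n_cols, f = filters;
  const arma::uword P0 = patchIdx.n_rows, mn = patchIdx.n_cols;
  const int nStages = args.size();

  std::vector<const int*> argPtr(nStages);
  std::vector<arma::uword> nOut(nStages);
  arma::uword maxPos = 0;
  for (int s = 0; s < nStages; ++s) {
    argPtr[s] = INTEGER(as<IntegerVector>(args[s]));
    nOut[s] = as<arma::umat>(poolIdx[s]).n_rows;
    maxPos = std::max(maxPos, nOut[s]);
  }

  const arma::mat Pall = gatherAll(tflat, patchIdx);
  arma::mat gK(mn, f, arma::fill::zeros);
  arma::vec gb(f, arma::fill::zeros);
  arma::mat buf1(maxPos, f), buf2(maxPos, f);

  for (arma::uword b = 0; b < B; ++b) {
    // gradient at the last pooling output, from the flattened layout
    arma::mat* cur = &buf1;
    const double* fr = Gfeat.memptr();
    for (arma::uword c = 0; c < f; ++c)
      for (arma::uword o = 0; o < nOut[nStages - 1]; ++o)
        buf1(o, c) = fr[b + B * (c * nOut[nStages - 1] + o)];
    // scatter back through pooling stages down to stage 1's outputs
    for (int s = nStages - 1; s >= 1; --s) {
      arma::mat& nxt = (cur == &buf1) ? buf2 : buf1;
      nxt.zeros(nOut[s - 1], f);
      const int* a = argPtr[s] + static_cast<R_xlen_t>(nOut[s]) * f * b;
      for (arma::uword c = 0; c < f; ++c)
        for (arma::uword o = 0; o < nOut[s]; ++o)
          nxt(a[o + nOut[s] * c], c) += (*cur)(o, c);
      cur = &nxt;
    }
    // stage 1: conv-position gradients exist only at kept argmax pixels
    const int* a1 = argPtr[0] + static_cast<R_xlen_t>(nOut[0]) * f * b;
    for (arma::uword c = 0; c < f; ++c)
      for (arma::uword o = 0; o < nOut[0]; ++o) {
        const int pos = a1[o + nOut[0] * c];
        if (pos < 0) continue;
        const double gm = (*cur)(o, c) * invKeep;
        if (gm == 0.0) continue;
        gb(c) += gm;
        const arma::uword r = b * P0 + static_cast<arma::uword>(pos);
        for (arma::uword e = 0; e < mn; ++e) gK(e, c) += gm * Pall(r, e);
      }
  }
  return List::create(Named("K") = gK, Named("b") = gb);
}
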