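#include <Rcpp.h>
#include <cmath>
#include <string>
#include <vector>
using namespace Rcpp;

// Unordered diploid genotypes over A,C,G,T in alphabetical order
// (AA, AC, AG, AT, CC, CG, CT, GG, GT, TT), 0-based allele indexes.
static const int GP1[10] = {0, 0, 0, 0, 1, 1, 1, 2, 2, 3};
static const int GP2[10] = {0, 1, 2, 3, 1, 2, 3, 2, 3, 3};

static inline int base_code(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default: return -1;
  }
}

// Log-likelihoods of the 10 genotypes for one sample at one site.
// bases: 0..3 codes; errs: per-read error probabilities.
// [[Rcpp::export]]
NumericVector cpp_gl_column(IntegerVector bases, NumericVector errs) {
  NumericVector ll(10);
  const int n = bases.size();
  for (int j = 0; j < n; ++j) {
    const int b = bases[j];
    const double e = errs[j];
    const double match = 1.0 - e, mis = e / 3.0;
    for (int g = 0; g < 10; ++g) {
      const double p1 = (b == GP1[g]) ? match : mis;
      const double p2 = (b == GP2[g]) ? match : mis;
      ll[g] += std::log(0.5 * (p1 + p2));
    }
  }
  double mx = ll[0];
  for (int g = 1; g < 10; ++g) if (ll[g] > mx) mx = ll[g];
  for (int g = 0; g < 10; ++g) ll[g] -= mx;
  return ll;
}

// Genotype log-likelihood array for a whole pileup.
// bases/quals: sites x samples character matrices; bases over ACGT,
// quals PHRED+33 ASCII. Returns 10 x S x N array (max-normalised per
// cell) plus the depth matrix.
// [[Rcpp::export]]
List cpp_gl_pileup(CharacterMatrix bases, CharacterMatrix quals, double cap) {
  const int S = bases.nrow(), N = bases.ncol();
  NumericVector gl(Dimension(10, S, N));
  IntegerMatrix depth(S, N);
  std::vector<double> ll(10);
  for (int j = 0; j < N; ++j) {
    for (int i = 0; i < S; ++i) {
      std::string b = as<std::string>(bases(i, j));
      std::string q = as<std::string>(quals(i, j));
      if (b.size() != q.size())
        stop("base/quality length mismatch at site %d, sample %d", i + 1, j + 1);
      const int d = (int) b.size();
      depth(i, j) = d;
      std::fill(ll.begin(), ll.end(), 0.0);
      for (int r = 0; r < d; ++r) {
        const int bc = base_code(b[r]);
        if (bc < 0) stop("invalid base '%c' at site %d, sample %d", b[r], i + 1, j + 1);
        const int ph = (int) q[r] - 33;
        if (ph < 0) stop("invalid quality character at site %d, sample %d", i + 1, j + 1);
        double e = std::pow(10.0, -ph / 10.0);
        if (e > cap) e = cap;
        const double match = 1.0 - e, mis = e / 3.0;
        for (int g = 0; g < 10; ++g) {
          const double p1 = (bc == GP1[g]) ? match : mis;
          const double p2 = (bc == GP2[g]) ? match : mis;
          ll[g] += std::log(0.5 * (p1 + p2));
        }
      }
      double mx = ll[0];
      for (int g = 1; g < 10; ++g) if (ll[g] > mx) mx = ll[g];
      const size_t off = (size_t) 10 * ((size_t) i + (size_t) S * j);
      for (int g = 0; g < 10; ++g) gl[off + g] = ll[g] - mx;
    }
  }
  return List::create(_["loglik"] = gl, _["depth"] = depth);
}

// Concatenate base codes / PHRED quals into per-cell strings
// (column-major cell order given by lens).
// [[Rcpp::export]]
List cpp_encode_reads(IntegerVector codes, IntegerVector phred, IntegerVector lens) {
  const int ncell = lens.size();
  CharacterVector bout(ncell), qout(ncell);
  static const char B[4] = {'A', 'C', 'G', 'T'};
  R_xlen_t pos = 0;
  for (int c = 0; c < ncell; ++c) {
    const int d = lens[c];
    std::string bs(d, 'N'), qs(d, '!');
    for (int r = 0; r < d; ++r) {
      bs[r] = B[codes[pos]];
      int ph = phred[pos];
      if (ph > 93) ph = 93;  // printable PHRED+33 range
      qs[r] = (char) (33 + ph);
      ++pos;
    }
    bout[c] = bs;
    qout[c] = qs;
  }
  return List::create(_["bases"] = bout, _["quals"] = qout);
}

// P(observed genotype dosage d | template alleles t1,t2, copying error eps)
static inline void copy_probs(int t1, int t2, double eps, double out[3]) {
  const double p1 = (t1 == 1) ? 1.0 - eps : eps;  // P(allele 1 = alt)
  const double p2 = (t2 == 1) ? 1.0 - eps : eps;
  out[0] = (1.0 - p1) * (1.0 - p2);
  out[1] = p1 * (1.0 - p2) + (1.0 - p1) * p2;
  out[2] = p1 * p2;
}

// Li-Stephens haplotype-copying HMM for one diploid sample.
//
// L:   M x 3 per-marker likelihood triplets (linear scale; flat rows for
//      masked / missing markers), columns = dosage 0,1,2 of the alt allele.
// H:   K x M reference haplotypes (0/1).
// rho: length M-1 per-interval switch probability.
// eps: length M per-marker per-allele copying error.
//
// Exact forward-backward marginals over the K^2 ordered-pair state space
// (transitions factorise per haplotype: stay w.p. 1-rho, else uniform over
// the K templates), plus one backward-sampled path with sampled allele pair,
// switch indicators and template mismatch count for self-calibration.
// [[Rcpp::export]]
List cpp_lshmm_sample(NumericMatrix L, IntegerMatrix H, NumericVector rho,
                      NumericVector eps, bool sample_path,
                      bool greedy_alleles = true) {
  const int M = L.nrow();
  const int K = H.nrow();
  if (K < 1) stop("at least one reference haplotype required");
  if (M < 1) stop("no markers");
  if (rho.size() != M - 1 && M > 1) stop("rho must have length M-1");
  if (eps.size() != M) stop("eps must have length M");

  // per-marker class emissions E(t1,t2) and copy tables (classes 2*t1+t2)
  std::vector<double> cls(4 * M), cpv(12 * M);
  for (int m = 0; m < M; ++m)
    for (int t = 0; t < 4; ++t) {
      double *cp = &cpv[12 * m + 3 * t];
      copy_probs(t >> 1, t & 1, eps[m], cp);
      cls[4 * m + t] = cp[0] * L(m, 0) + cp[1] * L(m, 1) + cp[2] * L(m, 2);
    }

  // contiguous per-marker emission vectors: E0[k] = E(0, h_k), E1[k] = E(1, h_k)
  const int *Hp = INTEGER(H);  // column-major: column m contiguous in k
  std::vector<double> E0((size_t) M * K), E1((size_t) M * K);
  for (int m = 0; m < M; ++m) {
    const int *hm = Hp + (size_t) m * K;
    const double c00 = cls[4 * m + 0], c01 = cls[4 * m + 1];
    const double c10 = cls[4 * m + 2], c11 = cls[4 * m + 3];
    double *e0 = &E0[(size_t) m * K], *e1 = &E1[(size_t) m * K];
    for (int k = 0; k < K; ++k) {
      e0[k] = hm[k] ? c01 : c00;
      e1[k] = hm[k] ? c11 : c10;
    }
  }

  // forward messages, normalised per marker, stored for backward sampling
  std::vector<double> fwd((size_t) M * K * K);
  std::vector<double> buf(K * K), rows(K), cols(K);
  double loglik = 0.0;

  {
    double s = 0.0;
    double *f0 = &fwd[0];
    const int *h0 = Hp;
    for (int j = 0; j < K; ++j) {
      const double *em = h0[j] ? &E1[0] : &E0[0];
      double *fr = f0 + (size_t) j * K;
      for (int k = 0; k < K; ++k) {
        fr[k] = em[k];
        s += em[k];
      }
    }
    if (s <= 0.0) stop("zero forward mass at marker 1");
    const double inv = 1.0 / s;
    for (int x = 0; x < K * K; ++x) f0[x] *= inv;
    loglik += std::log(s / (double) (K * K));
  }

  for (int m = 1; m < M; ++m) {
    const double *fp = &fwd[(size_t) (m - 1) * K * K];
    double *fc = &fwd[(size_t) m * K * K];
    const double q = 1.0 - rho[m - 1];
    const double r = rho[m - 1] / (double) K;
    const double qq = q * q, qr = q * r, rr = r * r;
    std::fill(rows.begin(), rows.end(), 0.0);
    std::fill(cols.begin(), cols.end(), 0.0);
    for (int j = 0; j < K; ++j) {
      const double *fr = fp + (size_t) j * K;
      double rj = 0.0;
      for (int k = 0; k < K; ++k) {
        rj += fr[k];
        cols[k] += fr[k];
      }
      rows[j] = rj;
    }
    const int *hm = Hp + (size_t) m * K;
    const double *e0 = &E0[(size_t) m * K], *e1 = &E1[(size_t) m * K];
    double s = 0.0;
    for (int j = 0; j < K; ++j) {
      const double *em = hm[j] ? e1 : e0;
      const double base = qr * rows[j] + rr;
      const double *fr = fp + (size_t) j * K;
      double *fo = fc + (size_t) j * K;
      double sj = 0.0;
      for (int k = 0; k < K; ++k) {
        const double v = (qq * fr[k] + base + qr * cols[k]) * em[k];
        fo[k] = v;
        sj += v;
      }
      s += sj;
    }
    if (s <= 0.0) stop("zero forward mass at marker %d", m + 1);
    const double inv = 1.0 / s;
    for (int x = 0; x < K * K; ++x) fc[x] *= inv;
    loglik += std::log(s);
  }

  // backward pass with genotype-posterior accumulation
  NumericMatrix post(M, 3);
  std::vector<double> bwd(K * K, 1.0 / (double) (K * K)), g(K * K);
  for (int m = M - 1; m >= 0; --m) {
    const double *fc = &fwd[(size_t) m * K * K];
    const int *hm = Hp + (size_t) m * K;
    // state posterior ~ fwd * bwd, collapsed to the 4 template classes
    double W[4] = {0, 0, 0, 0};
    for (int j = 0; j < K; ++j) {
      const double *fr = fc + (size_t) j * K;
      const double *br = &bwd[(size_t) j * K];
      double w0 = 0.0, w1 = 0.0;
      for (int k = 0; k < K; ++k) {
        const double w = fr[k] * br[k];
        if (hm[k]) w1 += w; else w0 += w;
      }
      W[2 * hm[j]] += w0;
      W[2 * hm[j] + 1] += w1;
    }
    const double tot = W[0] + W[1] + W[2] + W[3];
    double pd[3] = {0, 0, 0};
    for (int t = 0; t < 4; ++t) {
      if (W[t] <= 0.0) continue;
      const double e = cls[4 * m + t];
      const double wt = W[t] / (tot * e);
      const double *cp = &cpv[12 * m + 3 * t];
      for (int d = 0; d < 3; ++d) pd[d] += wt * cp[d] * L(m, d);
    }
    const double ps = pd[0] + pd[1] + pd[2];
    for (int d = 0; d < 3; ++d) post(m, d) = pd[d] / ps;

    if (m > 0) {
      const double q = 1.0 - rho[m - 1];
      const double r = rho[m - 1] / (double) K;
      const double qq = q * q, qr = q * r, rr = r * r;
      const double *e0 = &E0[(size_t) m * K], *e1 = &E1[(size_t) m * K];
      std::fill(cols.begin(), cols.end(), 0.0);
      double gs = 0.0;
      for (int j = 0; j < K; ++j) {
        const double *em = hm[j] ? e1 : e0;
        const double *br = &bwd[(size_t) j * K];
        double *gr = &g[(size_t) j * K];
        double rj = 0.0;
        for (int k = 0; k < K; ++k) {
          const double v = em[k] * br[k];
          gr[k] = v;
          rj += v;
          cols[k] += v;
        }
        rows[j] = rj;
        gs += rj;
      }
      double bs = 0.0;
      for (int j = 0; j < K; ++j) {
        const double base = qr * rows[j] + rr * gs;
        const double *gr = &g[(size_t) j * K];
        double *br = &buf[(size_t) j * K];
        double sj = 0.0;
        for (int k = 0; k < K; ++k) {
          const double v = qq * gr[k] + base + qr * cols[k];
          br[k] = v;
          sj += v;
        }
        bs += sj;
      }
      const double inv = 1.0 / bs;
      for (int x = 0; x < K * K; ++x) bwd[x] = buf[x] * inv;
    }
  }

  IntegerMatrix hap(2, M);
  IntegerVector switches(std::max(M - 1, 0));
  IntegerVector mism(M);
  if (sample_path) {
    RNGScope scope;
    std::vector<int> sj(M), sk(M);
    // sample final state from the forward filter
    {
      const double *fM = &fwd[(size_t) (M - 1) * K * K];
      double u = unif_rand(), acc = 0.0;
      int pick = K * K - 1;
      for (int x = 0; x < K * K; ++x) {
        acc += fM[x];
        if (u <= acc) { pick = x; break; }
      }
      sj[M - 1] = pick / K;
      sk[M - 1] = pick % K;
    }
    for (int m = M - 2; m >= 0; --m) {
      const double *fc = &fwd[(size_t) m * K * K];
      const int jn = sj[m + 1], kn = sk[m + 1];
      const double q = 1.0 - rho[m];
      const double r = rho[m] / (double) K;
      double rj = 0.0, ck = 0.0;
      for (int k = 0; k < K; ++k) rj += fc[jn * K + k];
      for (int j = 0; j < K; ++j) ck += fc[j * K + kn];
      const double w1 = q * q * fc[jn * K + kn];  // neither switches
      const double w2 = q * r * rj;               // k switches
      const double w3 = q * r * ck;               // j switches
      const double w4 = r * r;                    // both switch
      const double u = unif_rand() * (w1 + w2 + w3 + w4);
      if (u <= w1) {
        sj[m] = jn; sk[m] = kn; switches[m] = 0;
      } else if (u <= w1 + w2) {
        sj[m] = jn; switches[m] = 1;
        double v = unif_rand() * rj, acc = 0.0;
        int pick = K - 1;
        for (int k = 0; k < K; ++k) { acc += fc[jn * K + k]; if (v <= acc) { pick = k; break; } }
        sk[m] = pick;
      } else if (u <= w1 + w2 + w3) {
        sk[m] = kn; switches[m] = 1;
        double v = unif_rand() * ck, acc = 0.0;
        int pick = K - 1;
        for (int j = 0; j < K; ++j) { acc += fc[j * K + kn]; if (v <= acc) { pick = j; break; } }
        sj[m] = pick;
      } else {
        switches[m] = 2;
        double tot = 0.0;
        for (int x = 0; x < K * K; ++x) tot += fc[x];
        double v = unif_rand() * tot, acc = 0.0;
        int pick = K * K - 1;
        for (int x = 0; x < K * K; ++x) { acc += fc[x]; if (v <= acc) { pick = x; break; } }
        sj[m] = pick / K;
        sk[m] = pick % K;
      }
    }
    // sample the allele pair at each marker given the sampled templates
    for (int m = 0; m < M; ++m) {
      const int t1 = H(sj[m], m), t2 = H(sk[m], m);
      const double p1 = (t1 == 1) ? 1.0 - eps[m] : eps[m];
      const double p2 = (t2 == 1) ? 1.0 - eps[m] : eps[m];
      double w[4];
      w[0] = L(m, 0) * (1.0 - p1) * (1.0 - p2);  // (0,0)
      w[1] = L(m, 1) * (1.0 - p1) * p2;          // (0,1)
      w[2] = L(m, 1) * p1 * (1.0 - p2);          // (1,0)
      w[3] = L(m, 2) * p1 * p2;                  // (1,1)
      int a1, a2;
      if (greedy_alleles) {
        // best-guess allele pair: keeps eps-level noise out of the panel
        // at data-free markers (the copying path itself stays sampled)
        int best = 0;
        for (int x = 1; x < 4; ++x) if (w[x] > w[best]) best = x;
        a1 = best >> 1;
        a2 = best & 1;
      } else {
        const double tw = w[0] + w[1] + w[2] + w[3];
        const double u = unif_rand() * tw;
        if (u <= w[0]) { a1 = 0; a2 = 0; }
        else if (u <= w[0] + w[1]) { a1 = 0; a2 = 1; }
        else if (u <= w[0] + w[1] + w[2]) { a1 = 1; a2 = 0; }
        else { a1 = 1; a2 = 1; }
      }
      hap(0, m) = a1;
      hap(1, m) = a2;
      mism[m] += (a1 != t1) + (a2 != t2);
    }
  }

  return List::create(_["post"] = post, _["hap"] = hap,
                      _["switches"] = switches, _["mismatches"] = mism,
                      _["loglik"] = loglik);
}
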