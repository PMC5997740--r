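#include "penna.h"
#include <algorithm>
#include <set>

using namespace Rcpp;

void set_bit(uint64_t* w, int i) { w[i >> 6] |= (uint64_t)1 << (i & 63); }

int get_bit(const uint64_t* w, int i) {
  return (int)((w[i >> 6] >> (i & 63)) & 1);
}

int popcount_bits(const uint64_t* w, int nwords) {
  int n = 0;
  for (int i = 0; i < nwords; ++i) n += __builtin_popcountll(w[i]);
  return n;
}

void mutate_bits(uint64_t* w, int nbits, double mean, int dialect) {
  int k;
  if (dialect == MUT_BERNOULLI) {
    k = (unif_rand() < mean) ? 1 : 0;
  } else {
    k = (int)R::rpois(mean);
  }
  for (int i = 0; i < k; ++i) set_bit(w, rng_int(nbits));
}

std::vector<int> draw_crossover_points(int nbits, double mean, int dialect) {
  int maxp = nbits - 1;  // intergenic boundaries 1..nbits-1
  int k;
  if (dialect == CROSS_BERNOULLI) {
    k = (unif_rand() < mean) ? 1 : 0;
  } else {
    k = (int)R::rpois(mean);
  }
  if (k > maxp) k = maxp;
  std::vector<int> pts;
  if (k <= 0) return pts;
  // Floyd's sampling: k distinct boundaries from 1..maxp.
  std::set<int> s;
  for (int j = maxp - k + 1; j <= maxp; ++j) {
    int t = 1 + rng_int(j);
    if (!s.insert(t).second) s.insert(j);
  }
  pts.assign(s.begin(), s.end());
  return pts;
}

static void swap_suffix(uint64_t* a, uint64_t* b, int nbits, int p) {
  int w0 = p >> 6, off = p & 63, nw = words_for(nbits);
  if (off) {
    uint64_t mask = ~(uint64_t)0 << off;
    uint64_t t = (a[w0] ^ b[w0]) & mask;
    a[w0] ^= t;
    b[w0] ^= t;
    ++w0;
  }
  for (int i = w0; i < nw; ++i) std::swap(a[i], b[i]);
}

void crossover_bits(uint64_t* a, uint64_t* b, int nbits,
                    const std::vector<int>& points) {
  for (int p : points) swap_suffix(a, b, nbits, p);
}

int count_homo_window(const uint64_t* a, const uint64_t* b, int lo, int hi) {
  if (lo >= hi) return 0;
  int n = 0;
  int wlo = lo >> 6, whi = (hi - 1) >> 6;
  for (int w = wlo; w <= whi; ++w) {
    uint64_t m = ~(uint64_t)0;
    if (w == wlo) m &= ~(uint64_t)0 << (lo & 63);
    if (w == whi) {
      int r = hi - (w << 6);  // bits of this word inside the window
      if (r < 64) m &= (~(uint64_t)0) >> (64 - r);
    }
    n += __builtin_popcountll(a[w] & b[w] & m);
  }
  return n;
}

double mutate_modifier_core(double v, double step) {
  if (v == 0.0) return 0.0;  // absorbing state
  double d = (unif_rand() < 0.5) ? step : -step;
  double out = v + d;
  // values below epsilon are floating-point residue of an exact sequence of
  // decrements (e.g. 0.4 - 8*0.05 = 7.6e-17) and mean absorption at 0
  return out < 1e-9 ? 0.0 : out;
}

std::vector<std::pair<int, int>> torus_offsets(int side, int range) {
  std::vector<std::pair<int, int>> out;
  std::set<std::pair<int, int>> seen;
  for (int dr = -range; dr <= range; ++dr) {
    for (int dc = -range; dc <= range; ++dc) {
      if (dr == 0 && dc == 0) continue;
      int r = ((dr % side) + side) % side;
      int c = ((dc % side) + side) % side;
      if (r == 0 && c == 0) continue;
      if (seen.insert(std::make_pair(r, c)).second)
        out.push_back(std::make_pair(r, c));
    }
  }
  return out;
}

void pack_bits(const IntegerVector& bits, uint64_t* w) {
  int n = bits.size();
  std::fill(w, w + words_for(n), (uint64_t)0);
  for (int i = 0; i < n; ++i)
    if (bits[i]) set_bit(w, i);
}

IntegerVector unpack_bits(const uint64_t* w, int nbits) {
  IntegerVector out(nbits);
  for (int i = 0; i < nbits; ++i) out[i] = get_bit(w, i);
  return out;
}

// ---- exported primitives (thin wrappers over the same core the engine uses)

// [[Rcpp::export]]
IntegerVector cpp_mutate_chrom(IntegerVector bits, double mean, int dialect) {
  std::vector<uint64_t> w(words_for(bits.size()));
  pack_bits(bits, w.data());
  mutate_bits(w.data(), bits.size(), mean, dialect);
  return unpack_bits(w.data(), bits.size());
}

// [[Rcpp::export]]
List cpp_crossover_chrom(IntegerVector a, IntegerVector b, double mean,
                         int dialect) {
  int n = a.size();
  std::vector<uint64_t> wa(words_for(n)), wb(words_for(n));
  pack_bits(a, wa.data());
  pack_bits(b, wb.data());
  std::vector<int> pts = draw_crossover_points(n, mean, dialect);
  crossover_bits(wa.data(), wb.data(), n, pts);
  return List::create(_["a"] = unpack_bits(wa.data(), n),
                      _["b"] = unpack_bits(wb.data(), n),
                      _["points"] = IntegerVector(pts.begin(), pts.end()));
}

// [[Rcpp::export]]
List cpp_crossover_at(IntegerVector a, IntegerVector b, IntegerVector points) {
  int n = a.size();
  std::vector<uint64_t> wa(words_for(n)), wb(words_for(n));
  pack_bits(a, wa.data());
  pack_bits(b, wb.data());
  std::vector<int> pts(points.begin(), points.end());
  std::sort(pts.begin(), pts.end());
  crossover_bits(wa.data(), wb.data(), n, pts);
  return List::create(_["a"] = unpack_bits(wa.data(), n),
                      _["b"] = unpack_bits(wb.data(), n));
}

// [[Rcpp::export]]
List cpp_make_gamete_chrom(IntegerVector c0, IntegerVector c1, double mu,
                           int mut_dialect, double rec, int cross_dialect) {
  int n = c0.size();
  std::vector<uint64_t> w0(words_for(n)), w1(words_for(n));
  pack_bits(c0, w0.data());
  pack_bits(c1, w1.data());
  mutate_bits(w0.data(), n, mu, mut_dialect);
  mutate_bits(w1.data(), n, mu, mut_dialect);
  std::vector<int> pts = draw_crossover_points(n, rec, cross_dialect);
  crossover_bits(w0.data(), w1.data(), n, pts);
  int pick = rng_int(2);  // 0: product starting with c0's head, 1: c1's head
  const uint64_t* chosen = pick ? w1.data() : w0.data();
  return List::create(_["bits"] = unpack_bits(chosen, n), _["pick"] = pick);
}

// [[Rcpp::export]]
int cpp_count_homo_window(IntegerVector a, IntegerVector b, int lo, int hi) {
  int n = a.size();
  std::vector<uint64_t> wa(words_for(n)), wb(words_for(n));
  pack_bits(a, wa.data());
  pack_bits(b, wb.data());
  return count_homo_window(wa.data(), wb.data(), lo, hi);
}

// [[Rcpp::export]]
int cpp_popcount_chrom(IntegerVector bits) {
  int n = bits.size();
  std::vector<uint64_t> w(words_for(n));
  pack_bits(bits, w.data());
  return popcount_bits(w.data(), words_for(n));
}

// [[Rcpp::export]]
double cpp_mutate_modifier(double v, double step) {
  return mutate_modifier_core(v, step);
}

// [[Rcpp::export]]
IntegerMatrix cpp_torus_offsets(int side, int range) {
  std::vector<std::pair<int, int>> off = torus_offsets(side, range);
  IntegerMatrix out(off.size(), 2);
  for (size_t i = 0; i < off.size(); ++i) {
    out(i, 0) = off[i].first;
    out(i, 1) = off[i].second;
  }
  return out;
}
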