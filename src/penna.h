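#pragma once

#include <Rcpp.h>
#include <cstdint>
#include <vector>

// Dialect codes shared with the R layer (see scenario_config()).
#define MUT_BERNOULLI 0
#define MUT_POISSON 1
#define CROSS_POISSON 0
#define CROSS_BERNOULLI 1

inline int words_for(int nbits) { return (nbits + 63) / 64; }

// Uniform integer on 0..n-1 from R's RNG stream.
inline int rng_int(int n) {
  int k = (int)(unif_rand() * n);
  return k >= n ? n - 1 : k;
}

void set_bit(uint64_t* w, int i);
int get_bit(const uint64_t* w, int i);
int popcount_bits(const uint64_t* w, int nwords);

// One replication of a chromosome copy: 0->1 only, a hit on an existing 1
// consumes the event (no reversions).
void mutate_bits(uint64_t* w, int nbits, double mean, int dialect);

// Number of crossover points for one meiosis, distinct boundaries in
// 1..nbits-1, returned sorted ascending.
std::vector<int> draw_crossover_points(int nbits, double mean, int dialect);

// Reciprocal exchange at the given sorted boundaries (suffix swaps).
void crossover_bits(uint64_t* a, uint64_t* b, int nbits,
                    const std::vector<int>& points);

// Homozygous-defect count over the half-open locus window [lo, hi).
int count_homo_window(const uint64_t* a, const uint64_t* b, int lo, int hi);

// +/- step random walk on the X-Y recombination modifier, absorbing at 0.
double mutate_modifier_core(double v, double step);

// Unique toroidal Chebyshev-neighbourhood offsets (excluding (0,0)),
// deduplicated under wraparound when 2*range+1 >= side.
std::vector<std::pair<int, int>> torus_offsets(int side, int range);

void pack_bits(const Rcpp::IntegerVector& bits, uint64_t* w);
Rcpp::IntegerVector unpack_bits(const uint64_t* w, int nbits);
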