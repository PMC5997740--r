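#include "penna.h"
#include <algorithm>

using namespace Rcpp;

#define MATING_UNFAITHFUL 0
#define MATING_FAITHFUL 1
#define REGIME_OFF 0
#define REGIME_ON 1
#define REGIME_EVOLVING 2

namespace {

struct SpecC {
  int len;      // loci
  int k;        // loci activated per year = len / L
  int nwords;
  int off0;     // word offset of copy 0 within an individual's bit block
  int off1;     // copy 1 (Y in males for the sex pair)
  double mu;
  double rec;
};

struct Ind {
  std::vector<uint64_t> bits;
  int age = 0;
  int sex = 0;  // 0 female, 1 male
  int cum = 0;
  double mod = 0.0;  // effective X-Y recombination rate carried by males
  int partner = -1;
  int cell = -1;  // row * side + col; -1 when panmictic
  bool alive = false;
};

struct Engine {
  // config
  int side, steps, L, b, Rage, T, Dp, Dc;
  double B, modifier_step;
  int mating, regime, mut_dialect, cross_dialect;
  bool panmictic;
  int ceiling, record_every, comparator, sexpair;
  bool want_snapshot;
  double init_xy;

  std::vector<SpecC> specs;
  int total_words;

  std::vector<Ind> pool;
  std::vector<int> free_slots;
  std::vector<int> grid;  // cell -> pool index, -1 empty
  // free-cell registry: scanning it beats scanning the neighbourhood when
  // the lattice is nearly full (the steady state here)
  std::vector<int> free_cells;
  std::vector<int> free_pos;  // cell -> index in free_cells, -1 if occupied
  int n_alive = 0;
  std::vector<std::pair<int, int>> off_p, off_c;

  // scratch buffers for gamete formation
  std::vector<uint64_t> tmp0, tmp1, gam_m, gam_f;

  // recorded series
  std::vector<double> rec_step, rec_pop, rec_births, rec_deaths, rec_norm;
  std::vector<double> rec_nm[3], rec_nf[3], rec_fx[3], rec_fy[3], rec_fc[3];

  double sex_rate(const Ind& father) const {
    if (regime == REGIME_OFF) return 0.0;
    if (regime == REGIME_ON) return specs[sexpair].rec;
    return father.mod;
  }

  double male_mod_at_birth(const Ind& father) {
    if (regime == REGIME_OFF) return 0.0;
    if (regime == REGIME_ON) return specs[sexpair].rec;
    return mutate_modifier_core(father.mod, modifier_step);
  }

  double initial_mod() const {
    if (regime == REGIME_OFF) return 0.0;
    return specs[sexpair].rec;  // on: fixed; evolving: starts at the X-X rate
  }

  int new_slot() {
    if (!free_slots.empty()) {
      int i = free_slots.back();
      free_slots.pop_back();
      return i;
    }
    pool.push_back(Ind());
    pool.back().bits.assign(total_words, 0);
    return (int)pool.size() - 1;
  }

  void free_cell_add(int cell) {
    free_pos[cell] = (int)free_cells.size();
    free_cells.push_back(cell);
  }

  void free_cell_take(int cell) {
    int i = free_pos[cell];
    int last = free_cells.back();
    free_cells[i] = last;
    free_pos[last] = i;
    free_cells.pop_back();
    free_pos[cell] = -1;
  }

  void kill(int i) {
    Ind& d = pool[i];
    d.alive = false;
    if (d.cell >= 0) {
      grid[d.cell] = -1;
      free_cell_add(d.cell);
    }
    if (d.partner >= 0) {
      pool[d.partner].partner = -1;
      d.partner = -1;
    }
    free_slots.push_back(i);
    --n_alive;
  }

  int torus_cheby(int a, int b) const {
    int dr = std::abs(a / side - b / side);
    int dc = std::abs(a % side - b % side);
    dr = std::min(dr, side - dr);
    dc = std::min(dc, side - dc);
    return std::max(dr, dc);
  }

  void initialize() {
    int n0 = panmictic ? ceiling : side * side;
    pool.clear();
    free_slots.clear();
    pool.reserve(n0);
    grid.assign(panmictic ? 0 : side * side, -1);
    free_cells.clear();
    free_pos.assign(panmictic ? 0 : side * side, -1);
    n_alive = 0;
    for (int c = 0; c < n0; ++c) {
      pool.push_back(Ind());
      Ind& ind = pool.back();
      ind.bits.assign(total_words, 0);
      ind.alive = true;
      ind.sex = rng_int(2);
      ind.age = rng_int(L);
      ind.cum = 0;
      ind.partner = -1;
      ind.mod = (ind.sex == 1) ? initial_mod() : 0.0;
      if (!panmictic) {
        ind.cell = c;
        grid[c] = (int)pool.size() - 1;
      }
      ++n_alive;
    }
  }

  int aging_phase() {
    int deaths = 0;
    int np = (int)pool.size();
    for (int i = 0; i < np; ++i) {
      Ind& ind = pool[i];
      if (!ind.alive) continue;
      ++ind.age;
      if (ind.age >= L) {
        kill(i);
        ++deaths;
        continue;
      }
      if (ind.age >= b) {
        for (const SpecC& s : specs) {
          ind.cum += count_homo_window(ind.bits.data() + s.off0,
                                       ind.bits.data() + s.off1,
                                       ind.age * s.k, (ind.age + 1) * s.k);
        }
        if (ind.cum >= T) {
          kill(i);
          ++deaths;
        }
      }
    }
    return deaths;
  }

  // builds one gamete chromosome; returns which product was picked (0 =
  // starts with copy0's head, 1 = copy1's head)
  int gamete_spec(const Ind& par, const SpecC& s, double recrate,
                  uint64_t* dst) {
    const uint64_t* c0 = par.bits.data() + s.off0;
    const uint64_t* c1 = par.bits.data() + s.off1;
    std::copy(c0, c0 + s.nwords, tmp0.data());
    std::copy(c1, c1 + s.nwords, tmp1.data());
    mutate_bits(tmp0.data(), s.len, s.mu, mut_dialect);
    mutate_bits(tmp1.data(), s.len, s.mu, mut_dialect);
    std::vector<int> pts = draw_crossover_points(s.len, recrate, cross_dialect);
    crossover_bits(tmp0.data(), tmp1.data(), s.len, pts);
    int pick = rng_int(2);
    std::copy(pick ? tmp1.data() : tmp0.data(),
              (pick ? tmp1.data() : tmp0.data()) + s.nwords, dst);
    return pick;
  }

  // one conception attempt for mother m; returns true on a live birth
  bool attempt(int m) {
    Ind& mom = pool[m];
    // collect candidate child cells first; in unfaithful mode an attempt
    // with no vacancy in range can fail before the (side-effect free)
    // partner scan, in faithful mode bonding must still happen first
    if (!panmictic) {
      collect_free_cells(mom.cell);
      if (mating == MATING_UNFAITHFUL && cand_cells.empty()) return false;
    }
    // (1) partner
    int father = -1;
    if (mating == MATING_FAITHFUL) {
      if (mom.partner < 0) {
        int pick = pick_male(mom, /*unpaired_only=*/true);
        if (pick < 0) return false;
        mom.partner = pick;
        pool[pick].partner = m;
      }
      father = mom.partner;
    } else {
      father = pick_male(mom, /*unpaired_only=*/false);
      if (father < 0) return false;
    }
    // (2) free place for the child
    int child_cell = -1;
    if (panmictic) {
      if (n_alive >= ceiling) return false;
    } else {
      if (cand_cells.empty()) return false;
      child_cell = cand_cells[rng_int((int)cand_cells.size())];
    }
    // (3)-(4) gametes and zygote
    Ind& dad = pool[father];
    int child_sex = 0;
    int cum0 = 0;
    for (size_t si = 0; si < specs.size(); ++si) {
      const SpecC& s = specs[si];
      uint64_t* gm = gam_m.data() + s.off0;  // maternal haplotype -> copy 0
      uint64_t* gf = gam_m.data() + s.off1;  // paternal haplotype -> copy 1
      gamete_spec(mom, s, s.rec, gm);
      double rr = ((int)si == sexpair) ? sex_rate(dad) : s.rec;
      int pick = gamete_spec(dad, s, rr, gf);
      // sex pair: copy0 of a male is X, copy1 is Y; the crossover product
      // keeping the Y's chromosome head is the Y (positional convention)
      if ((int)si == sexpair && dad.sex == 1 && pick == 1) child_sex = 1;
      // (5) prenatal check on loci activated before the birth age b
      cum0 += count_homo_window(gm, gf, 0, b * s.k);
    }
    if (cum0 >= T) return false;  // zygotic death
    // place the newborn
    int slot = new_slot();
    Ind& kid = pool[slot];
    std::copy(gam_m.begin(), gam_m.end(), kid.bits.begin());
    kid.alive = true;
    kid.age = 0;
    kid.sex = child_sex;
    kid.cum = cum0;
    kid.partner = -1;
    kid.mod = (child_sex == 1) ? male_mod_at_birth(pool[father]) : 0.0;
    kid.cell = child_cell;
    if (!panmictic) {
      grid[child_cell] = slot;
      free_cell_take(child_cell);
    }
    ++n_alive;
    return true;
  }

  std::vector<int> cand, cand_cells;  // reusable candidate buffers

  int pick_male(const Ind& mom, bool unpaired_only) {
    cand.clear();
    if (panmictic) {
      int np = (int)pool.size();
      for (int i = 0; i < np; ++i) {
        const Ind& x = pool[i];
        if (x.alive && x.sex == 1 && x.age >= Rage &&
            (!unpaired_only || x.partner < 0))
          cand.push_back(i);
      }
    } else {
      int r0 = mom.cell / side, c0 = mom.cell % side;
      for (const std::pair<int, int>& o : off_p) {
        int cell = ((r0 + o.first) % side) * side + (c0 + o.second) % side;
        int i = grid[cell];
        if (i < 0) continue;
        const Ind& x = pool[i];
        if (x.sex == 1 && x.age >= Rage && (!unpaired_only || x.partner < 0))
          cand.push_back(i);
      }
    }
    if (cand.empty()) return -1;
    return cand[rng_int((int)cand.size())];
  }

  void collect_free_cells(int from) {
    cand_cells.clear();
    if (free_cells.size() < off_c.size()) {
      for (int cell : free_cells)
        if (cell != from && torus_cheby(cell, from) <= Dc)
          cand_cells.push_back(cell);
    } else {
      int r0 = from / side, c0 = from % side;
      for (const std::pair<int, int>& o : off_c) {
        int cell = ((r0 + o.first) % side) * side + (c0 + o.second) % side;
        if (grid[cell] < 0) cand_cells.push_back(cell);
      }
    }
  }

  int reproduction_phase() {
    // mothers processed in random order
    std::vector<int> moms;
    int np = (int)pool.size();
    for (int i = 0; i < np; ++i)
      if (pool[i].alive && pool[i].sex == 0 && pool[i].age >= Rage)
        moms.push_back(i);
    for (int i = (int)moms.size() - 1; i > 0; --i)
      std::swap(moms[i], moms[rng_int(i + 1)]);
    int births = 0;
    for (int m : moms) {
      int n = (int)R::rpois(B);
      for (int a = 0; a < n; ++a) {
        if (attempt(m)) {  // first success ends her attempts this step
          ++births;
          break;
        }
      }
    }
    return births;
  }

  void record(int step, int births, int deaths) {
    // cohorts: 0 newborns (age 0), 1 youths (0 < age < R), 2 adults (>= R)
    double nm[3] = {0, 0, 0}, nf[3] = {0, 0, 0};
    double dx[3] = {0, 0, 0}, nx[3] = {0, 0, 0};
    double dy[3] = {0, 0, 0}, ny[3] = {0, 0, 0};
    double dc[3] = {0, 0, 0}, nc[3] = {0, 0, 0};
    double modsum = 0;
    int nmales = 0;
    const SpecC& sx = specs[sexpair];
    const SpecC& sc = specs[comparator];
    for (const Ind& ind : pool) {
      if (!ind.alive) continue;
      int coh = ind.age == 0 ? 0 : (ind.age < Rage ? 1 : 2);
      if (ind.sex == 1) {
        nm[coh] += 1;
        modsum += ind.mod;
        ++nmales;
        // male sex pair: copy0 = X, copy1 = Y
        dx[coh] += popcount_bits(ind.bits.data() + sx.off0, sx.nwords);
        nx[coh] += 1;
        dy[coh] += popcount_bits(ind.bits.data() + sx.off1, sx.nwords);
        ny[coh] += 1;
      } else {
        nf[coh] += 1;
        dx[coh] += popcount_bits(ind.bits.data() + sx.off0, sx.nwords) +
                   popcount_bits(ind.bits.data() + sx.off1, sx.nwords);
        nx[coh] += 2;
      }
      dc[coh] += popcount_bits(ind.bits.data() + sc.off0, sc.nwords) +
                 popcount_bits(ind.bits.data() + sc.off1, sc.nwords);
      nc[coh] += 2;
    }
    rec_step.push_back(step);
    rec_pop.push_back(n_alive);
    rec_births.push_back(births);
    rec_deaths.push_back(deaths);
    rec_norm.push_back(nmales > 0 && init_xy > 0
                           ? (modsum / nmales) / init_xy
                           : NA_REAL);
    for (int c = 0; c < 3; ++c) {
      rec_nm[c].push_back(nm[c]);
      rec_nf[c].push_back(nf[c]);
      rec_fx[c].push_back(nx[c] > 0 ? dx[c] / (nx[c] * sx.len) : NA_REAL);
      rec_fy[c].push_back(ny[c] > 0 ? dy[c] / (ny[c] * sx.len) : NA_REAL);
      rec_fc[c].push_back(nc[c] > 0 ? dc[c] / (nc[c] * sc.len) : NA_REAL);
    }
  }

  List locus_profiles() {
    const SpecC& sx = specs[sexpair];
    const SpecC& sc = specs[comparator];
    std::vector<double> px(sx.len, 0), py(sx.len, 0), pc(sc.len, 0);
    double nxc = 0, nyc = 0, ncc = 0;
    for (const Ind& ind : pool) {
      if (!ind.alive) continue;
      const uint64_t* x0 = ind.bits.data() + sx.off0;
      const uint64_t* x1 = ind.bits.data() + sx.off1;
      if (ind.sex == 1) {
        for (int i = 0; i < sx.len; ++i) px[i] += get_bit(x0, i);
        nxc += 1;
        for (int i = 0; i < sx.len; ++i) py[i] += get_bit(x1, i);
        nyc += 1;
      } else {
        for (int i = 0; i < sx.len; ++i)
          px[i] += get_bit(x0, i) + get_bit(x1, i);
        nxc += 2;
      }
      const uint64_t* a0 = ind.bits.data() + sc.off0;
      const uint64_t* a1 = ind.bits.data() + sc.off1;
      for (int i = 0; i < sc.len; ++i) pc[i] += get_bit(a0, i) + get_bit(a1, i);
      ncc += 2;
    }
    NumericVector vx(sx.len, NA_REAL), vy(sx.len, NA_REAL),
        vc(sc.len, NA_REAL);
    for (int i = 0; i < sx.len; ++i) {
      if (nxc > 0) vx[i] = px[i] / nxc;
      if (nyc > 0) vy[i] = py[i] / nyc;
    }
    for (int i = 0; i < sc.len; ++i)
      if (ncc > 0) vc[i] = pc[i] / ncc;
    return List::create(_["X"] = vx, _["Y"] = vy, _["comparator"] = vc);
  }

  List snapshot() {
    List out(n_alive);
    int j = 0;
    for (const Ind& ind : pool) {
      if (!ind.alive) continue;
      List pairs(specs.size());
      for (size_t si = 0; si < specs.size(); ++si) {
        const SpecC& s = specs[si];
        pairs[si] = List::create(
            _["a"] = unpack_bits(ind.bits.data() + s.off0, s.len),
            _["b"] = unpack_bits(ind.bits.data() + s.off1, s.len));
      }
      out[j++] = List::create(
          _["sex"] = ind.sex, _["age"] = ind.age, _["cum_defects"] = ind.cum,
          _["xy_modifier"] = ind.mod,
          _["row"] = ind.cell >= 0 ? ind.cell / side : NA_INTEGER,
          _["col"] = ind.cell >= 0 ? ind.cell % side : NA_INTEGER,
          _["genome"] = pairs);
    }
    return out;
  }
};

}  // namespace

// [[Rcpp::export]]
List cpp_run_simulation(List cfg) {
  Engine e;
  e.side = as<int>(cfg["lattice_side"]);
  e.steps = as<int>(cfg["steps"]);
  e.L = as<int>(cfg["basic_length"]);
  e.b = as<int>(cfg["birth_check"]);
  e.Rage = as<int>(cfg["repro_age"]);
  e.T = as<int>(cfg["death_threshold"]);
  e.B = as<double>(cfg["attempts_mean"]);
  e.Dp = as<int>(cfg["partner_range"]);
  e.Dc = as<int>(cfg["child_range"]);
  e.mating = as<int>(cfg["mating_code"]);
  e.regime = as<int>(cfg["regime_code"]);
  e.modifier_step = as<double>(cfg["modifier_step"]);
  e.mut_dialect = as<int>(cfg["mutation_dialect_code"]);
  e.cross_dialect = as<int>(cfg["crossover_dialect_code"]);
  e.panmictic = as<bool>(cfg["panmictic"]);
  e.ceiling = as<int>(cfg["ceiling"]);
  e.record_every = as<int>(cfg["record_every"]);
  e.comparator = as<int>(cfg["comparator_index"]);  // 0-based
  e.sexpair = as<int>(cfg["sexpair_index"]);
  e.want_snapshot = as<bool>(cfg["snapshot"]);

  IntegerVector lens = cfg["lengths"];
  NumericVector mus = cfg["mutation_means"];
  NumericVector recs = cfg["recomb_means"];
  int off = 0, maxw = 0;
  for (int i = 0; i < lens.size(); ++i) {
    SpecC s;
    s.len = lens[i];
    s.k = s.len / e.L;
    s.nwords = words_for(s.len);
    s.mu = mus[i];
    s.rec = recs[i];
    s.off0 = off;
    off += s.nwords;
    s.off1 = off;
    off += s.nwords;
    e.specs.push_back(s);
    if (s.nwords > maxw) maxw = s.nwords;
  }
  e.total_words = off;
  e.tmp0.assign(maxw, 0);
  e.tmp1.assign(maxw, 0);
  e.gam_m.assign(off, 0);
  e.init_xy = e.specs[e.sexpair].rec;
  if (!e.panmictic) {
    e.off_p = torus_offsets(e.side, e.Dp);
    e.off_c = torus_offsets(e.side, e.Dc);
  }

  e.initialize();
  e.record(0, 0, 0);
  bool extinct = false;
  int last_step = 0;
  for (int step = 1; step <= e.steps; ++step) {
    int deaths = e.aging_phase();
    int births = (e.n_alive > 0) ? e.reproduction_phase() : 0;
    last_step = step;
    if (e.n_alive == 0) {
      e.record(step, births, deaths);
      extinct = true;
      break;
    }
    if (step % e.record_every == 0 || step == e.steps)
      e.record(step, births, deaths);
    if (step % 2048 == 0) Rcpp::checkUserInterrupt();
  }

  List series = List::create(
      _["step"] = wrap(e.rec_step), _["pop_size"] = wrap(e.rec_pop),
      _["births"] = wrap(e.rec_births), _["deaths"] = wrap(e.rec_deaths),
      _["mean_norm_xy_recomb"] = wrap(e.rec_norm));
  const char* coh[3] = {"newborns", "youths", "adults"};
  for (int c = 0; c < 3; ++c) {
    series[std::string("n_males_") + coh[c]] = wrap(e.rec_nm[c]);
    series[std::string("n_females_") + coh[c]] = wrap(e.rec_nf[c]);
    series[std::string("frac_X_") + coh[c]] = wrap(e.rec_fx[c]);
    series[std::string("frac_Y_") + coh[c]] = wrap(e.rec_fy[c]);
    series[std::string("frac_comparator_") + coh[c]] = wrap(e.rec_fc[c]);
  }

  List out = List::create(
      _["series"] = series, _["profiles"] = e.locus_profiles(),
      _["extinct"] = extinct, _["final_step"] = last_step,
      _["final_pop"] = e.n_alive, _["initial_xy_rate"] = e.init_xy);
  if (e.want_snapshot) out["snapshot"] = e.snapshot();
  return out;
}
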