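// Hudson's algorithm for the exact coalescent with recombination, operating
// on ancestral segments (l, r, u) and emitting coalescence records.
//
// All stochastic draws use R's RNG so that runs are reproducible via
// set.seed().  The draw sequence per event is fixed and is mirrored
// exactly by the pure-R reference engine (R/hudson-r-engine.R):
//   1. exp_rand() * (1/total_rate)          -- waiting time
//   2. unif_rand() < rec_rate/total_rate    -- event type
//   3. recombination: unif_rand() -> link index in 1..L
//      common ancestor: unif_rand() -> i, unif_rand() -> j (j != i)
// Any change here must be applied to both engines.

#include <Rcpp.h>
#include <map>
#include <vector>

namespace {

struct Seg {
  int l, r, u;
};

// Fenwick tree over dense population positions; supports O(log N) prefix
// sums and searching for the ancestor holding the h-th link.
class Fenwick {
  std::vector<long long> f;  // 1-based
  int cap, highbit;

 public:
  void rebuild(const std::vector<long long> &vals, int capacity) {
    cap = capacity;
    f.assign(cap + 1, 0);
    highbit = 1;
    while ((highbit << 1) <= cap) highbit <<= 1;
    for (int i = 1; i <= (int)vals.size(); ++i) add(i, vals[i - 1]);
  }
  int capacity() const { return cap; }
  void add(int i, long long d) {
    for (; i <= cap; i += i & (-i)) f[i] += d;
  }
  long long prefix(int i) const {
    long long s = 0;
    for (; i > 0; i -= i & (-i)) s += f[i];
    return s;
  }
  // smallest position p with prefix(p) >= h  (assumes 1 <= h <= total)
  int search(long long h) const {
    int pos = 0;
    long long rem = h - 1;
    for (int pw = highbit; pw > 0; pw >>= 1) {
      int nxt = pos + pw;
      if (nxt <= cap && f[nxt] <= rem) {
        pos = nxt;
        rem -= f[nxt];
      }
    }
    return pos + 1;
  }
};

inline long long seg_links(const std::vector<Seg> &a) {
  return (long long)a.back().r - a.front().l - 1;
}

class Simulation {
 public:
  int n, m;
  double rho;
  double max_events;

  std::vector<std::vector<Seg> > pop;  // dense list
  std::vector<long long> links;        // links per ancestor, parallel to pop
  long long L;                         // sum of links
  Fenwick fen;
  std::map<int, int> ov;  // overlap counts: key -> #segments on [key, next)
  double t;
  int w;

  // emitted records
  std::vector<int> rl, rr_, ru, rc1, rc2;
  std::vector<double> rt;

  double n_rec, n_rec_anc, n_ca, n_coal;

  Simulation(int n_, int m_, double rho_, double max_events_)
      : n(n_), m(m_), rho(rho_), max_events(max_events_) {
    pop.reserve(2 * n);
    links.assign(n, (long long)(m - 1));
    for (int u = 1; u <= n; ++u) {
      std::vector<Seg> a(1);
      a[0].l = 0;
      a[0].r = m;
      a[0].u = u;
      pop.push_back(a);
    }
    L = (long long)n * (m - 1);
    fen.rebuild(links, std::max(2 * n, 16));
    ov[0] = n;
    ov[m] = 0;
    t = 0.0;
    w = n + 1;
    n_rec = n_rec_anc = n_ca = n_coal = 0.0;
  }

  void append(std::vector<Seg> &a) {
    long long la = seg_links(a);
    pop.push_back(std::vector<Seg>());
    pop.back().swap(a);
    links.push_back(la);
    if ((int)links.size() > fen.capacity())
      fen.rebuild(links, 2 * fen.capacity());
    else
      fen.add((int)links.size(), la);
    L += la;
  }

  // remove dense position p (1-based) by swapping the last element in
  void remove_at(int p) {
    int last = (int)pop.size();
    L -= links[p - 1];
    if (p != last) {
      fen.add(p, links[last - 1] - links[p - 1]);
      links[p - 1] = links[last - 1];
      pop[p - 1].swap(pop[last - 1]);
    }
    fen.add(last, -links[last - 1]);
    links.pop_back();
    pop.pop_back();
  }

  // make sure x is a key of the overlap map (0 < x < m)
  std::map<int, int>::iterator ensure_key(int x) {
    std::map<int, int>::iterator it = ov.lower_bound(x);
    if (it == ov.end() || it->first != x) {
      std::map<int, int>::iterator prev = it;
      --prev;
      it = ov.insert(it, std::make_pair(x, prev->second));
    }
    return it;
  }

  void recombination_event() {
    long long h = (long long)std::floor(unif_rand() * (double)L) + 1;
    if (h > L) h = L;
    int p = fen.search(h);
    long long off = h - fen.prefix(p - 1);
    std::vector<Seg> &a = pop[p - 1];
    int k = a.front().l + (int)off;

    bool inside = false, junction = false;
    std::vector<Seg> left, right;
    for (size_t i = 0; i < a.size(); ++i) {
      const Seg &s = a[i];
      if (s.r <= k) {
        left.push_back(s);
        if (s.r == k && i + 1 < a.size() && a[i + 1].l == k) junction = true;
      } else if (s.l >= k) {
        right.push_back(s);
      } else {  // s.l < k < s.r: straddling segment is split
        inside = true;
        Seg sl = s, sr = s;
        sl.r = k;
        sr.l = k;
        left.push_back(sl);
        right.push_back(sr);
      }
    }
    n_rec += 1;
    if (inside || junction) n_rec_anc += 1;

    long long ll = seg_links(left);
    fen.add(p, ll - links[p - 1]);
    L += ll - links[p - 1];
    links[p - 1] = ll;
    pop[p - 1].swap(left);
    append(right);
  }

  void common_ancestor_event() {
    int N = (int)pop.size();
    int i0 = (int)std::floor(unif_rand() * N);
    if (i0 >= N) i0 = N - 1;
    int j0 = (int)std::floor(unif_rand() * (N - 1));
    if (j0 >= N - 1) j0 = N - 2;
    if (j0 >= i0) ++j0;

    std::vector<Seg> a, b;
    a.swap(pop[i0]);
    b.swap(pop[j0]);
    int p = std::max(i0, j0) + 1, q = std::min(i0, j0) + 1;
    remove_at(p);
    remove_at(q);
    n_ca += 1;

    std::vector<Seg> out;
    out.reserve(a.size() + b.size());
    bool coalesced = false;
    size_t ia = 0, ib = 0;
    while (ia < a.size() && ib < b.size()) {
      Seg &x = a[ia];
      Seg &y = b[ib];
      if (x.r <= y.l) {  // x entirely left of y: passes through
        out.push_back(x);
        ++ia;
        continue;
      }
      if (y.r <= x.l) {
        out.push_back(y);
        ++ib;
        continue;
      }
      if (x.l < y.l) {  // left overhang of x
        Seg s = x;
        s.r = y.l;
        out.push_back(s);
        x.l = y.l;
        continue;
      }
      if (y.l < x.l) {
        Seg s = y;
        s.r = x.l;
        out.push_back(s);
        y.l = x.l;
        continue;
      }
      // exact intersection on [l, r): a coalescence event
      int l = x.l;
      int r = std::min(x.r, y.r);
      coalesced = true;
      n_coal += 1;
      rl.push_back(l);
      rr_.push_back(r);
      ru.push_back(w);
      rc1.push_back(std::min(x.u, y.u));
      rc2.push_back(std::max(x.u, y.u));
      rt.push_back(t);
      // update overlap counts; retain the merged segment only where other
      // ancestral material still intersects
      ensure_key(l);
      ensure_key(r);
      std::map<int, int>::iterator it = ov.find(l);
      while (it->first < r) {
        std::map<int, int>::iterator nx = it;
        ++nx;
        if (it->second == 2) {
          it->second = 0;  // fully coalesced: MRCA reached here
        } else {
          it->second -= 1;
          Seg s;
          s.l = it->first;
          s.r = nx->first;
          s.u = w;
          out.push_back(s);
        }
        it = nx;
      }
      if (x.r == r) ++ia; else x.l = r;
      if (y.r == r) ++ib; else y.l = r;
    }
    for (; ia < a.size(); ++ia) out.push_back(a[ia]);
    for (; ib < b.size(); ++ib) out.push_back(b[ib]);

    // defragment: merge touching segments mapped to the same node
    std::vector<Seg> d;
    d.reserve(out.size());
    for (size_t i = 0; i < out.size(); ++i) {
      if (!d.empty() && d.back().u == out[i].u && d.back().r == out[i].l)
        d.back().r = out[i].r;
      else
        d.push_back(out[i]);
    }
    if (coalesced) ++w;
    if (!d.empty()) append(d);
  }

  void run() {
    double n_events = 0.0;
    while (!pop.empty()) {
      int N = (int)pop.size();
      if (N < 2)
        Rcpp::stop("internal error: single non-empty ancestor remaining");
      double rec_rate = (m > 1) ? rho * (double)L / (m - 1) : 0.0;
      double ca_rate = (double)N * (N - 1);
      double total = rec_rate + ca_rate;
      double scale = 1.0 / total;
      t += exp_rand() * scale;
      if (++n_events > max_events)
        Rcpp::stop("event cap exceeded (%.0f events): raise max_events",
                   max_events);
      if (unif_rand() < rec_rate / total)
        recombination_event();
      else
        common_ancestor_event();
    }
    for (std::map<int, int>::iterator it = ov.begin(); it != ov.end(); ++it) {
      if (it->first < m && it->second != 0)
        Rcpp::stop("internal error: ancestral material not fully coalesced");
    }
  }
};

}  // namespace

// [[Rcpp::export(.hudson_sim_cpp)]]
Rcpp::List hudson_sim_cpp(int n, int m, double rho, double max_events) {
  Simulation sim(n, m, rho, max_events);
  sim.run();
  return Rcpp::List::create(
      Rcpp::Named("left") = Rcpp::wrap(sim.rl),
      Rcpp::Named("right") = Rcpp::wrap(sim.rr_),
      Rcpp::Named("node") = Rcpp::wrap(sim.ru),
      Rcpp::Named("child1") = Rcpp::wrap(sim.rc1),
      Rcpp::Named("child2") = Rcpp::wrap(sim.rc2),
      Rcpp::Named("time") = Rcpp::wrap(sim.rt),
      Rcpp::Named("n_recombination") = sim.n_rec,
      Rcpp::Named("n_recomb_ancestral") = sim.n_rec_anc,
      Rcpp::Named("n_common_ancestor") = sim.n_ca,
      Rcpp::Named("n_coalescence") = sim.n_coal);
}
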