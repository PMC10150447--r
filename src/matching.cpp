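#include <Rcpp.h>
#include <vector>
#include <deque>
#include <algorithm>

// Exact maximum weight matching on a general graph (blossom algorithm,
// O(n^3) with dual variables and slack bookkeeping).  Weights are supplied
// as non-negative 64-bit integers (the R wrapper scales doubles); ties are
// broken arbitrarily but deterministically.  Vertices are 1-based here;
// blossoms occupy ids n+1 .. 2n.

namespace {

typedef long long ll;
const ll INF = (ll)1e18;

struct Edge {
  int u, v;
  ll w;
};

struct Blossom {
  int n, n_x;
  std::vector<std::vector<Edge> > g;
  std::vector<ll> lab;
  std::vector<int> match, slack, st, pa, S, vis;
  std::vector<std::vector<int> > flower, flower_from;
  std::deque<int> q;

  explicit Blossom(int n_) : n(n_) {
    int m = n * 2 + 1;
    g.assign(m, std::vector<Edge>(m));
    for (int u = 0; u < m; ++u)
      for (int v = 0; v < m; ++v)
        g[u][v] = (Edge){u, v, 0};
    lab.assign(m, 0);
    match.assign(m, 0);
    slack.assign(m, 0);
    st.assign(m, 0);
    pa.assign(m, 0);
    S.assign(m, 0);
    vis.assign(m, 0);
    flower.assign(m, std::vector<int>());
    flower_from.assign(m, std::vector<int>(n + 1, 0));
  }

  ll e_delta(const Edge& e) const { return lab[e.u] + lab[e.v] - g[e.u][e.v].w * 2; }

  void update_slack(int u, int x) {
    if (!slack[x] || e_delta(g[u][x]) < e_delta(g[slack[x]][x])) slack[x] = u;
  }

  void set_slack(int x) {
    slack[x] = 0;
    for (int u = 1; u <= n; ++u)
      if (g[u][x].w > 0 && st[u] != x && S[st[u]] == 0) update_slack(u, x);
  }

  void q_push(int x) {
    if (x <= n) {
      q.push_back(x);
    } else {
      for (size_t i = 0; i < flower[x].size(); ++i) q_push(flower[x][i]);
    }
  }

  void set_st(int x, int b) {
    st[x] = b;
    if (x > n)
      for (size_t i = 0; i < flower[x].size(); ++i) set_st(flower[x][i], b);
  }

  int get_pr(int b, int xr) {
    int pr = (int)(std::find(flower[b].begin(), flower[b].end(), xr) - flower[b].begin());
    if (pr % 2 == 1) {
      std::reverse(flower[b].begin() + 1, flower[b].end());
      return (int)flower[b].size() - pr;
    }
    return pr;
  }

  void set_match(int u, int v) {
    match[u] = g[u][v].v;
    if (u > n) {
      Edge e = g[u][v];
      int xr = flower_from[u][e.u];
      int pr = get_pr(u, xr);
      for (int i = 0; i < pr; ++i) set_match(flower[u][i], flower[u][i ^ 1]);
      set_match(xr, v);
      std::rotate(flower[u].begin(), flower[u].begin() + pr, flower[u].end());
    }
  }

  void augment(int u, int v) {
    for (;;) {
      int xnv = st[match[u]];
      set_match(u, v);
      if (!xnv) return;
      set_match(xnv, st[pa[xnv]]);
      u = st[pa[xnv]];
      v = xnv;
    }
  }

  int get_lca(int u, int v) {
    static int t = 0;
    for (++t; u || v; std::swap(u, v)) {
      if (u == 0) continue;
      if (vis[u] == t) return u;
      vis[u] = t;
      u = st[match[u]];
      if (u) u = st[pa[u]];
    }
    return 0;
  }

  void add_blossom(int u, int lca, int v) {
    int b = n + 1;
    while (b <= n_x && st[b]) ++b;
    if (b > n_x) ++n_x;
    lab[b] = 0;
    S[b] = 0;
    match[b] = match[lca];
    flower[b].clear();
    flower[b].push_back(lca);
    for (int x = u, y; x != lca; x = st[pa[y]]) {
      flower[b].push_back(x);
      flower[b].push_back(y = st[match[x]]);
      q_push(y);
    }
    std::reverse(flower[b].begin() + 1, flower[b].end());
    for (int x = v, y; x != lca; x = st[pa[y]]) {
      flower[b].push_back(x);
      flower[b].push_back(y = st[match[x]]);
      q_push(y);
    }
    set_st(b, b);
    for (int x = 1; x <= n_x; ++x) g[b][x].w = g[x][b].w = 0;
    for (int x = 1; x <= n; ++x) flower_from[b][x] = 0;
    for (size_t i = 0; i < flower[b].size(); ++i) {
      int xs = flower[b][i];
      for (int x = 1; x <= n_x; ++x)
        if (g[b][x].w == 0 || e_delta(g[xs][x]) < e_delta(g[b][x])) {
          g[b][x] = g[xs][x];
          g[x][b] = g[x][xs];
        }
      for (int x = 1; x <= n; ++x)
        if (flower_from[xs][x]) flower_from[b][x] = xs;
    }
    set_slack(b);
  }

  void expand_blossom(int b) {
    for (size_t i = 0; i < flower[b].size(); ++i) set_st(flower[b][i], flower[b][i]);
    int xr = flower_from[b][g[b][pa[b]].u];
    int pr = get_pr(b, xr);
    for (int i = 0; i < pr; i += 2) {
      int xs = flower[b][i], xns = flower[b][i + 1];
      pa[xs] = g[xns][xs].u;
      S[xs] = 1;
      S[xns] = 0;
      slack[xs] = 0;
      set_slack(xns);
      q_push(xns);
    }
    S[xr] = 1;
    pa[xr] = pa[b];
    for (size_t i = pr + 1; i < flower[b].size(); ++i) {
      int xs = flower[b][i];
      S[xs] = -1;
      set_slack(xs);
    }
    st[b] = 0;
  }

  bool on_found_edge(const Edge& e) {
    int u = st[e.u], v = st[e.v];
    if (S[v] == -1) {
      pa[v] = e.u;
      S[v] = 1;
      int nu = st[match[v]];
      slack[v] = slack[nu] = 0;
      S[nu] = 0;
      q_push(nu);
    } else if (S[v] == 0) {
      int lca = get_lca(u, v);
      if (!lca) {
        augment(u, v);
        augment(v, u);
        return true;
      }
      add_blossom(u, lca, v);
    }
    return false;
  }

  bool matching_round() {
    std::fill(S.begin(), S.begin() + n_x + 1, -1);
    std::fill(slack.begin(), slack.begin() + n_x + 1, 0);
    q.clear();
    for (int x = 1; x <= n_x; ++x)
      if (st[x] == x && !match[x]) {
        pa[x] = 0;
        S[x] = 0;
        q_push(x);
      }
    if (q.empty()) return false;
    for (;;) {
      while (!q.empty()) {
        int u = q.front();
        q.pop_front();
        if (S[st[u]] == 1) continue;
        for (int v = 1; v <= n; ++v)
          if (g[u][v].w > 0 && st[u] != st[v]) {
            if (e_delta(g[u][v]) == 0) {
              if (on_found_edge(g[u][v])) return true;
            } else {
              update_slack(u, st[v]);
            }
          }
      }
      ll d = INF;
      for (int b = n + 1; b <= n_x; ++b)
        if (st[b] == b && S[b] == 1) d = std::min(d, lab[b] / 2);
      for (int x = 1; x <= n_x; ++x)
        if (st[x] == x && slack[x]) {
          if (S[x] == -1)
            d = std::min(d, e_delta(g[slack[x]][x]));
          else if (S[x] == 0)
            d = std::min(d, e_delta(g[slack[x]][x]) / 2);
        }
      for (int u = 1; u <= n; ++u) {
        if (S[st[u]] == 0) {
          if (lab[u] <= d) return false;
          lab[u] -= d;
        } else if (S[st[u]] == 1) {
          lab[u] += d;
        }
      }
      for (int b = n + 1; b <= n_x; ++b)
        if (st[b] == b) {
          if (S[b] == 0)
            lab[b] += d * 2;
          else if (S[b] == 1)
            lab[b] -= d * 2;
        }
      q.clear();
      for (int x = 1; x <= n_x; ++x)
        if (st[x] == x && slack[x] && st[slack[x]] != x && e_delta(g[slack[x]][x]) == 0)
          if (on_found_edge(g[slack[x]][x])) return true;
      for (int b = n + 1; b <= n_x; ++b)
        if (st[b] == b && S[b] == 1 && lab[b] == 0) expand_blossom(b);
    }
    return false;
  }

  void solve() {
    std::fill(match.begin(), match.end(), 0);
    n_x = n;
    for (int u = 0; u <= n; ++u) {
      st[u] = u;
      flower[u].clear();
    }
    ll w_max = 0;
    for (int u = 1; u <= n; ++u)
      for (int v = 1; v <= n; ++v) {
        flower_from[u][v] = (u == v ? u : 0);
        w_max = std::max(w_max, g[u][v].w);
      }
    for (int u = 1; u <= n; ++u) lab[u] = w_max;
    while (matching_round()) {
    }
  }
};

}  // namespace

// [[Rcpp::export]]
Rcpp::IntegerVector blossom_matching(Rcpp::IntegerVector ei, Rcpp::IntegerVector ej,
                                     Rcpp::NumericVector w, int n) {
  if (n <= 0) return Rcpp::IntegerVector(0);
  Blossom B(n);
  // scale to integers; similarities/counts here are well within 1e9 so a
  // 1e6 multiplier keeps everything inside long long with room to spare
  const double scale = 1e6;
  for (int k = 0; k < ei.size(); ++k) {
    int u = ei[k], v = ej[k];
    if (u < 1 || u > n || v < 1 || v > n || u == v)
      Rcpp::stop("invalid edge endpoint in matching input");
    ll wi = (ll)std::llround(w[k] * scale);
    if (wi <= 0) continue;  // non-positive edges can never improve a maximum
    if (wi > B.g[u][v].w) {
      B.g[u][v].w = wi;
      B.g[v][u].w = wi;
    }
  }
  B.solve();
  Rcpp::IntegerVector mate(n);
  for (int u = 1; u <= n; ++u) mate[u - 1] = B.match[u];
  return mate;
}
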