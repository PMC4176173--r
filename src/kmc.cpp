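#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Fixed-timestep kinetic Monte Carlo run of the elongation lattice model.
//
// Complexes are stored sorted by decreasing position (downstream first);
// forward motion with hard exclusion cannot reorder them. Per timestep the
// complexes are updated downstream-to-upstream (or in a random order), then
// initiation is attempted. A complex at active-site position p occupies
// lattice sites [p, p+d-1]; termination removes it once p would exceed L.
//
// All randomness comes from R's RNG (seed with set.seed() before calling).
//
// [[Rcpp::export]]
List cpp_kmc_run(const int L,
                 const IntegerVector pause_sites,
                 const double alpha,
                 const double epsilon,
                 const double f,
                 const double tau,
                 const int d,
                 const double dt,
                 const int n_steps,
                 const int record_every,
                 const bool keep_snapshots,
                 const IntegerVector init_pos,
                 const IntegerVector init_state,
                 const bool random_order,
                 const int probe_early_end,
                 const int probe_late_end,
                 const int stat_start_step)
{
    std::vector<char> is_pause(static_cast<size_t>(L) + 2, 0);
    for (int k = 0; k < pause_sites.size(); ++k) is_pause[pause_sites[k]] = 1;

    // state vectors, sorted by decreasing position
    std::vector<int> pos(init_pos.begin(), init_pos.end());
    std::vector<char> state(init_state.size());
    for (int k = 0; k < init_state.size(); ++k)
        state[k] = static_cast<char>(init_state[k]);
    const int n0 = static_cast<int>(pos.size());
    std::vector<int> id(n0);
    std::vector<double> birth(n0, 0.0);
    for (int k = 0; k < n0; ++k) id[k] = k + 1;
    int next_id = n0 + 1;

    long initiated = n0;   // preloaded complexes count as initiated
    long completed = 0;

    const double p_step   = epsilon * dt;
    const double p_stall  = f * dt;
    const double p_rescue = (tau > 0.0) ? dt / tau : 1.0;
    const double p_init   = alpha * dt;

    // recorded series
    std::vector<double> rec_time;
    std::vector<int> rec_init, rec_comp, rec_early, rec_late, rec_n;
    std::vector<std::vector<int> > snap_pos, snap_state, snap_id;
    std::vector<double> completion_times;

    // post-burn-in flux accounting
    long steps_accepted = 0;
    double ec_time = 0.0;
    long completed_post = 0;

    std::vector<char> alive;
    std::vector<int> order;

    for (int t = 1; t <= n_steps; ++t) {
        const int n = static_cast<int>(pos.size());
        const bool count_stats = (t > stat_start_step);
        if (count_stats) ec_time += n * dt;

        if (n > 0) {
            alive.assign(n, 1);
            bool any_removed = false;

            if (random_order) {
                order.resize(n);
                for (int i = 0; i < n; ++i) order[i] = i;
                for (int i = n - 1; i > 0; --i) {
                    int j = static_cast<int>(unif_rand() * (i + 1));
                    if (j > i) j = i;
                    std::swap(order[i], order[j]);
                }
            }

            for (int k = 0; k < n; ++k) {
                const int i = random_order ? order[k] : k;
                if (state[i] == 1) {                  // stalled: rescue?
                    if (unif_rand() < p_rescue) state[i] = 0;
                    continue;
                }
                const int p = pos[i];
                if (is_pause[p] && unif_rand() < p_stall) {  // stall first
                    state[i] = 1;
                    continue;
                }
                if (unif_rand() >= p_step) continue;  // no step attempt
                const int np = p + 1;
                if (np > L) {                          // terminate
                    alive[i] = 0;
                    any_removed = true;
                    ++completed;
                    if (count_stats) { ++completed_post; ++steps_accepted; }
                    completion_times.push_back(t * dt);
                    continue;
                }
                int j = i - 1;                         // nearest live downstream
                while (j >= 0 && !alive[j]) --j;
                if (j >= 0 && pos[j] - np < d) continue;  // excluded
                pos[i] = np;
                if (count_stats) ++steps_accepted;
            }

            if (any_removed) {                         // compact
                int w = 0;
                for (int i = 0; i < n; ++i) {
                    if (!alive[i]) continue;
                    pos[w] = pos[i]; state[w] = state[i];
                    id[w] = id[i]; birth[w] = birth[i];
                    ++w;
                }
                pos.resize(w); state.resize(w); id.resize(w); birth.resize(w);
            }
        } else if (p_init <= 0.0) {
            break;                                     // nothing can ever happen
        }

        // initiation, attempted last, only if the promoter region [1, d] is free
        const bool promoter_free = pos.empty() || pos.back() > d;
        if (promoter_free && p_init > 0.0 && unif_rand() < p_init) {
            pos.push_back(1);
            state.push_back(0);
            id.push_back(next_id++);
            birth.push_back(t * dt);
            ++initiated;
        }

        if (record_every > 0 && t % record_every == 0) {
            rec_time.push_back(t * dt);
            rec_init.push_back(static_cast<int>(initiated));
            rec_comp.push_back(static_cast<int>(completed));
            rec_n.push_back(static_cast<int>(pos.size()));
            if (probe_early_end > 0) {
                int e = 0, l = 0;
                for (size_t i = 0; i < pos.size(); ++i) {
                    if (pos[i] > probe_early_end) ++e;
                    if (pos[i] > probe_late_end) ++l;
                }
                rec_early.push_back(e + static_cast<int>(completed));
                rec_late.push_back(l + static_cast<int>(completed));
            }
            if (keep_snapshots) {
                snap_pos.push_back(pos);
                snap_state.push_back(std::vector<int>(state.begin(), state.end()));
                snap_id.push_back(id);
            }
        }
    }

    // if the run ended early (empty lattice, no initiation possible), pad the
    // recorded series out to the full grid with the frozen final state
    if (record_every > 0) {
        const int n_rec = n_steps / record_every;
        while (static_cast<int>(rec_time.size()) < n_rec) {
            const int t = (static_cast<int>(rec_time.size()) + 1) * record_every;
            rec_time.push_back(t * dt);
            rec_init.push_back(static_cast<int>(initiated));
            rec_comp.push_back(static_cast<int>(completed));
            rec_n.push_back(static_cast<int>(pos.size()));
            if (probe_early_end > 0) {
                rec_early.push_back(static_cast<int>(completed));
                rec_late.push_back(static_cast<int>(completed));
            }
            if (keep_snapshots) {
                snap_pos.push_back(pos);
                snap_state.push_back(std::vector<int>(state.begin(), state.end()));
                snap_id.push_back(id);
            }
        }
    }

    List snaps = R_NilValue;
    if (keep_snapshots) {
        const int m = static_cast<int>(snap_pos.size());
        List sp(m), ss(m), si(m);
        for (int k = 0; k < m; ++k) {
            sp[k] = wrap(snap_pos[k]);
            ss[k] = wrap(snap_state[k]);
            si[k] = wrap(snap_id[k]);
        }
        snaps = List::create(_["position"] = sp, _["state"] = ss, _["id"] = si);
    }

    return List::create(
        _["time"] = wrap(rec_time),
        _["initiated"] = wrap(rec_init),
        _["completed"] = wrap(rec_comp),
        _["n_on_lattice"] = wrap(rec_n),
        _["early"] = wrap(rec_early),
        _["late"] = wrap(rec_late),
        _["snapshots"] = snaps,
        _["completion_times"] = wrap(completion_times),
        _["total_initiated"] = static_cast<double>(initiated),
        _["total_completed"] = static_cast<double>(completed),
        _["completed_post"] = static_cast<double>(completed_post),
        _["steps_accepted"] = static_cast<double>(steps_accepted),
        _["ec_time"] = ec_time,
        _["final_position"] = wrap(pos),
        _["final_state"] = wrap(std::vector<int>(state.begin(), state.end())),
        _["final_id"] = wrap(id));
}
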