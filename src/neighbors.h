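#ifndef BEADCT_NEIGHBORS_H
#define BEADCT_NEIGHBORS_H

#include <vector>
#include <array>
#include <cstdlib>

// 3D neighbor offsets for 6/18/26 connectivity on an isotropic grid.
// 6  : face neighbors
// 18 : face + edge neighbors
// 26 : face + edge + vertex neighbors
inline std::vector<std::array<int, 3>> neighbor_offsets(int connectivity) {
    std::vector<std::array<int, 3>> off;
    for (int dz = -1; dz <= 1; ++dz)
        for (int dy = -1; dy <= 1; ++dy)
            for (int dx = -1; dx <= 1; ++dx) {
                int s = std::abs(dx) + std::abs(dy) + std::abs(dz);
                if (s == 0) continue;
                if (connectivity == 6 && s > 1) continue;
                if (connectivity == 18 && s > 2) continue;
                off.push_back({dx, dy, dz});
            }
    return off;
}

#endif
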