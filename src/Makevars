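# The BPTT core is elementwise-bound (exp/log activations, Gaussian noise);
# build it with vectorization-friendly flags. An explicit rule is needed
# because the site Makeconf appends its own -O2/-march after PKG_CXXFLAGS.
all: $(SHLIB)

NATFLAGS = -O3 -ffast-math -fopenmp-simd -march=native -fPIC \
  -DARMA_DONT_PRINT_FAST_MATH_WARNING

rnn.o: rnn.cpp
	$(CXX) -std=gnu++17 $(ALL_CPPFLAGS) $(NATFLAGS) -c rnn.cpp -o rnn.o
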