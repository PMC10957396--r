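# Build with the system C++ toolchain: the R distribution's configured
# cross-compiler targets a newer glibc than the runtime loader provides,
# so objects it produces cannot be dyn.load()ed here.
CXX = g++ -std=gnu++17
RCPP_INC = $(shell "$(R_HOME)/bin/Rscript" -e 'cat(system.file("include", package = "Rcpp"))')
PKG_CPPFLAGS = -I"$(RCPP_INC)"
OBJECTS = conc_nll.o RcppExports.o

all: glampi.so

glampi.so: $(OBJECTS)
	$(CXX) -shared -o $@ $(OBJECTS)

%.o: %.cpp
	$(CXX) $(ALL_CPPFLAGS) $(ALL_CXXFLAGS) -c $< -o $@

clean:
	@rm -f $(OBJECTS) glampi.so

.PHONY: all clean
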