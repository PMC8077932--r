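the
to
a
and
of
in
is
it
you
that
was
for
on
are
with
they
at
be
this
have
from
or
one
had
by
but
not
what
all
we
when
your
can
said
there
use
an
each
which
she
do
how
their
if
will
up
other
about
out
many
then
them
so
some
her
would
him
into
has
look
two
more
go
see
no
way
could
my
than
first
been
who
its
now
did
get
come
made
may
part
i
im
ive
me
am
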