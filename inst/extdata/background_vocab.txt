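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
make
like
him
into
time
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
day
did
get
come
made
may
part
today
work
home
school
game
music
movie
coffee
morning
night
week
weekend
rain
sun
city
street
car
bus
phone
internet
news
book
story
show
watch
play
win
match
goal
feel
feeling
better
year
month
new
old
big
small
long
really
very
just
still
never
always
again
going
want
good
great
happy
love
nice
fun
awesome
excited
glad
hope
bad
sad
angry
hate
awful
terrible
annoyed
upset
worried
cry
friend
family
people
talk
party
team
mom
dad
everyone
together
think
know
because
reason
maybe
remember
idea
question
wonder
sure
sleep
eat
food
tired
pain
head
body
sick
gym
run
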